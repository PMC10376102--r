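#' Specification of a synthetic backbone ensemble
#'
#' Describes one chain's simulated ensemble: per-residue mean torsions and
#' per-residue angular noise (wrapped-normal standard deviation, degrees).
#' Building the ensemble and running it through dihedral extraction and
#' label computation recovers `sigma / 180` as the planted fluctuation
#' profile.
#'
#' @param L Chain length (residues).
#' @param M Number of models.
#' @param sigma_phi Per-residue angular noise SD for phi, degrees (recycled
#'   to length L).
#' @param sigma_psi Same for psi; defaults to `sigma_phi`.
#' @param base_phi,base_psi Per-residue mean torsions, degrees (recycled).
#'   Defaults are an extended-chain geometry.
#' @param sequence Optional one-letter sequence; random standard residues
#'   by default.
#' @param chain_id Chain identifier.
#' @param seed Integer seed; all draws are reproducible from it.
#' @return Object of class `taf_ensemble_spec`.
#' @export
ensemble_spec <- function(L, M, sigma_phi, sigma_psi = sigma_phi,
                          base_phi = -120, base_psi = 135,
                          sequence = NULL, chain_id = "synth", seed = 1) {
  stopifnot(L >= 1, M >= 1, all(sigma_phi >= 0), all(sigma_psi >= 0))
  structure(list(L = as.integer(L), M = as.integer(M),
                 sigma_phi = rep_len(sigma_phi, L),
                 sigma_psi = rep_len(sigma_psi, L),
                 base_phi = rep_len(base_phi, L),
                 base_psi = rep_len(base_psi, L),
                 sequence = sequence, chain_id = chain_id,
                 seed = as.integer(seed)),
            class = "taf_ensemble_spec")
}

#' Simulate a multi-model backbone ensemble with planted angular noise
#'
#' For each model, per-residue phi/psi are drawn from a wrapped normal
#' around the spec's base angles with the spec's per-residue SDs, and
#' coordinates are rebuilt with [build_backbone()]. Identical seeds give
#' bitwise-identical coordinates.
#'
#' @param spec An [ensemble_spec()].
#' @return A [taf_ensemble()].
#' @export
synth_ensemble <- function(spec) {
  stopifnot(inherits(spec, "taf_ensemble_spec"))
  withr::with_seed(spec$seed, {
    sequence <- spec$sequence %||%
      paste(sample(AA_STANDARD, spec$L, replace = TRUE), collapse = "")
    models <- lapply(seq_len(spec$M), function(m) {
      phi <- wrap_angle(rnorm(spec$L, spec$base_phi, spec$sigma_phi))
      psi <- wrap_angle(rnorm(spec$L, spec$base_psi, spec$sigma_psi))
      build_backbone(phi, psi)
    })
    taf_ensemble(spec$chain_id, sequence, models)
  })
}

#' Specification of a planted-signal feature/label simulation
#'
#' Chains of uniform-random features with labels built from a known linear
#' combination of a few informative columns (optionally at neighbour
#' offsets, giving the labels a known windowed structure) plus Gaussian
#' noise, clipped into [0, 1].
#'
#' Defaults are the selection study conditions: 10 chains of 50 residues
#' (500 rows), 50 columns of which 5 evenly spaced ones are informative
#' with equal weights summing to 1, central residue only, noise SD 0.1.
#'
#' @param n_chains Number of chains.
#' @param chain_length Residues per chain (recycled to `n_chains`).
#' @param D Number of feature columns.
#' @param informative Indices of informative columns.
#' @param coefficients Weight per informative column (recycled); the
#'   default splits a total weight of 1 evenly.
#' @param offsets Residue offsets at which the informative columns act
#'   (0 = the residue itself, -1/+1 its neighbours). Each coefficient is
#'   applied at every offset, scaled by 1/length(offsets). Out-of-chain
#'   offsets contribute zero.
#' @param noise_sd SD of the additive Gaussian label noise.
#' @param intercept Constant added before clipping.
#' @param seed Integer seed.
#' @return Object of class `taf_signal_spec`.
#' @export
signal_spec <- function(n_chains = 10, chain_length = 50, D = 50,
                        informative = NULL, coefficients = NULL,
                        offsets = 0, noise_sd = 0.1, intercept = 0,
                        seed = 1) {
  informative <- informative %||% unique(round(seq(1, D, length.out = 5)))
  stopifnot(all(informative >= 1), all(informative <= D), noise_sd >= 0)
  coefficients <- rep_len(coefficients %||% (1 / length(informative)),
                          length(informative))
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = rep_len(as.integer(chain_length), n_chains),
                 D = as.integer(D), informative = as.integer(informative),
                 coefficients = coefficients, offsets = as.integer(offsets),
                 noise_sd = noise_sd, intercept = intercept,
                 seed = as.integer(seed)),
            class = "taf_signal_spec")
}

#' Simulate per-residue features with a planted label signal
#'
#' @param spec A [signal_spec()].
#' @return List with `features` (a `taf_features` tibble over all chains,
#'   columns `f1` ... `fD`, group `"synthetic"`) and `labels` (tibble of
#'   `chain_id`, `residue_index`, `y`). The `"truth"` attribute on
#'   `features` records the informative columns, coefficients and offsets.
#' @export
synth_features <- function(spec) {
  stopifnot(inherits(spec, "taf_signal_spec"))
  withr::with_seed(spec$seed, {
    chains <- lapply(seq_len(spec$n_chains), function(ci) {
      Lc <- spec$chain_length[ci]
      X <- matrix(runif(Lc * spec$D), nrow = Lc,
                  dimnames = list(NULL, paste0("f", seq_len(spec$D))))
      signal <- rep(spec$intercept, Lc)
      for (k in seq_along(spec$informative)) {
        col <- X[, spec$informative[k]]
        for (o in spec$offsets) {
          src <- seq_len(Lc) + o
          contrib <- ifelse(src >= 1 & src <= Lc, col[pmin(pmax(src, 1), Lc)], 0)
          contrib[src < 1 | src > Lc] <- 0
          signal <- signal + spec$coefficients[k] * contrib / length(spec$offsets)
        }
      }
      y <- pmin(pmax(signal + rnorm(Lc, 0, spec$noise_sd), 0), 1)
      id <- sprintf("synth_%02d", ci)
      list(features = bind_cols(tibble(chain_id = id,
                                       residue_index = seq_len(Lc) - 1L),
                                as_tibble(X)),
           labels = tibble(chain_id = id, residue_index = seq_len(Lc) - 1L,
                           y = y))
    })
  })
  features <- bind_rows(lapply(chains, `[[`, "features"))
  groups <- tibble(column = paste0("f", seq_len(spec$D)), group = "synthetic")
  features <- new_taf_features(features, groups)
  attr(features, "truth") <- list(informative = spec$informative,
                                  coefficients = spec$coefficients,
                                  offsets = spec$offsets)
  list(features = features,
       labels = bind_rows(lapply(chains, `[[`, "labels")))
}

#' Write a synthetic chain's full feature-input fixture tree
#'
#' Emits, under `dir/<chain_id>/`, the per-chain input files the feature
#' stage consumes -- `sequence.fasta`, `pssm.txt` (PSI-BLAST ASCII layout),
#' `asa.tsv`, `ss.tsv`, `ss_balanced.tsv`, `disorder.tsv`,
#' `pred_fluct.tsv`, `psee.tsv` -- with seeded random contents. Useful as a
#' format-conformance fixture for the command-line feature stage.
#'
#' @param sequence One-letter amino-acid sequence.
#' @param dir Root fixtures directory.
#' @param chain_id Chain identifier (subdirectory name).
#' @param seed Integer seed.
#' @return The chain directory path, invisibly.
#' @export
write_feature_fixture <- function(sequence, dir, chain_id = "synth", seed = 1) {
  L <- nchar(sequence)
  cdir <- file.path(dir, chain_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(seed, {
    writeLines(c(paste0(">", chain_id), sequence),
               file.path(cdir, "sequence.fasta"))
    scores <- matrix(sample(-8:8, L * 20L, replace = TRUE), nrow = L)
    write_pssm(scores, sequence, file.path(cdir, "pssm.txt"))
    readr::write_tsv(tibble(asa = runif(L, 0, 200)),
                     file.path(cdir, "asa.tsv"))
    rand_probs <- function() {
      p <- matrix(runif(L * 3L), nrow = L)
      p <- p / rowSums(p)
      tibble(H = p[, 1], C = p[, 2], E = p[, 3])
    }
    readr::write_tsv(rand_probs(), file.path(cdir, "ss.tsv"))
    readr::write_tsv(rand_probs(), file.path(cdir, "ss_balanced.tsv"))
    readr::write_tsv(tibble(disorder = runif(L)),
                     file.path(cdir, "disorder.tsv"))
    readr::write_tsv(tibble(dphi = runif(L), dpsi = runif(L)),
                     file.path(cdir, "pred_fluct.tsv"))
    readr::write_tsv(tibble(psee = rnorm(L)), file.path(cdir, "psee.tsv"))
  })
  invisible(cdir)
}
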