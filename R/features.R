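#' Amino-acid five-factor physicochemical table
#'
#' The compact five-factor numerical summary of amino-acid properties
#' (polarity, secondary-structure propensity, molecular volume, codon
#' diversity, electrostatic charge), one standardised score per factor per
#' standard amino acid. Shipped as a plain CSV under `extdata`.
#'
#' @return Tibble with columns `aa` and the five `pc_*` factor scores.
#' @export
aa_factor_table <- function() {
  path <- system.file("extdata", "aa_five_factors.csv", package = "torsionflux",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

check_sequence <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), AA_STANDARD)
  if (length(bad) > 0L) {
    abort(sprintf("nonstandard residue letter(s): %s (run dataset filters first)",
                  paste(bad, collapse = ", ")))
  }
  aa
}

#' Residue profile: one-hot encoding of the sequence
#'
#' One indicator column per standard amino acid, fixed alphabetical order
#' (ACDEFGHIKLMNPQRSTVWY); each row sums to one.
#'
#' @param sequence One-letter amino-acid string (standard residues only).
#' @return L x 20 tibble with columns `aa_A` ... `aa_Y`.
#' @export
residue_profile <- function(sequence) {
  aa <- check_sequence(sequence)
  m <- matrix(0, nrow = length(aa), ncol = 20L,
              dimnames = list(NULL, paste0("aa_", AA_STANDARD)))
  m[cbind(seq_along(aa), match(aa, AA_STANDARD))] <- 1
  as_tibble(m)
}

#' Physicochemical profile: five-factor lookup per residue
#'
#' @param sequence One-letter amino-acid string.
#' @param factor_table A 20-row table with column `aa` and one column per
#'   factor; defaults to [aa_factor_table()].
#' @return L x 5 tibble of factor scores.
#' @export
physiochemical_profile <- function(sequence, factor_table = aa_factor_table()) {
  aa <- check_sequence(sequence)
  miss <- setdiff(unique(aa), factor_table$aa)
  if (length(miss) > 0L) {
    abort(sprintf("factor table lacks rows for: %s", paste(miss, collapse = ", ")))
  }
  factor_table[match(aa, factor_table$aa), setdiff(names(factor_table), "aa")]
}

#' Load and normalise a PSSM
#'
#' Reads a position-specific scoring matrix in the PSI-BLAST ASCII layout
#' (the first 20 score columns) or, as a fallback, a TSV with an `aa` column
#' plus 20 score columns. Integer log-odds scores are mapped into (0, 1)
#' with the logistic transform 1 / (1 + exp(-x)).
#'
#' @param path Path to the PSSM file.
#' @param sequence Optional sequence; if given, the row count is checked
#'   against its length.
#' @return L x 20 tibble with columns `pssm_A` ... `pssm_Y` in (0, 1).
#' @export
load_pssm <- function(path, sequence = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  body <- grep("^\\s*\\d+\\s+[A-Z]\\s+-?\\d", lines, value = TRUE)
  if (length(body) > 0L) {
    scores <- do.call(rbind, lapply(body, function(ln) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      as.numeric(toks[3:22])
    }))
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    score_cols <- intersect(c(AA_STANDARD, paste0("pssm_", AA_STANDARD)), names(tab))
    if (length(score_cols) != 20L) {
      abort(sprintf("malformed PSSM file: %s", path))
    }
    scores <- as.matrix(tab[, score_cols])
  }
  if (anyNA(scores)) abort(sprintf("malformed PSSM file: %s", path))
  if (!is.null(sequence) && nrow(scores) != nchar(sequence)) {
    abort(sprintf("PSSM has %d rows but the sequence has %d residues",
                  nrow(scores), nchar(sequence)))
  }
  norm <- 1 / (1 + exp(-scores))
  colnames(norm) <- paste0("pssm_", AA_STANDARD)
  as_tibble(norm)
}

#' Write a PSSM fixture in the PSI-BLAST ASCII layout
#'
#' Counterpart of [load_pssm()], used by the synthetic-fixture generator so
#' that the reader is exercised on the real format.
#'
#' @param scores L x 20 matrix of integer log-odds scores.
#' @param sequence One-letter sequence of length L.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(scores, sequence, path) {
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(nrow(scores) == length(aa), ncol(scores) == 20L)
  hdr <- c("", "Last position-specific scoring matrix computed",
           paste0("            ", paste(sprintf("%3s", AA_STANDARD), collapse = " ")))
  rows <- vapply(seq_along(aa), function(i) {
    paste0(sprintf("%5d %s ", i, aa[i]),
           paste(sprintf("%3d", round(scores[i, ])), collapse = " "))
  }, "")
  writeLines(c(hdr, rows, ""), path)
  invisible(path)
}

#' Monogram feature from a normalised PSSM
#'
#' Per-residue mean of the 20 normalised profile values.
#'
#' @param pssm L x 20 tibble/matrix of normalised scores.
#' @return L x 1 tibble with column `mg`.
#' @export
monogram <- function(pssm) {
  m <- as.matrix(pssm)
  if (ncol(m) != 20L) abort("`pssm` must have 20 columns")
  tibble(mg = rowMeans(m))
}

#' Bigram features from a normalised PSSM
#'
#' Expected forward-transition products: BG_k(i) = (1/20) sum_j P(i, j) *
#' P(i+1, k). The last residue, which has no successor, falls back to a
#' self-transition (P(i+1) = P(i)).
#'
#' @param pssm L x 20 tibble/matrix of normalised scores.
#' @return L x 20 tibble with columns `bg_A` ... `bg_Y`.
#' @export
bigram <- function(pssm) {
  m <- as.matrix(pssm)
  if (nrow(m) < 1L) abort("`pssm` must have at least one row")
  if (ncol(m) != 20L) abort("`pssm` must have 20 columns")
  nxt <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
  bg <- rowMeans(m) * nxt
  colnames(bg) <- paste0("bg_", AA_STANDARD)
  as_tibble(bg)
}

clip_probs <- function(x, what) {
  out_of_range <- sum(x < 0 | x > 1, na.rm = TRUE)
  if (out_of_range > 0L) {
    warn(sprintf("%d %s value(s) outside [0, 1]; clipping", out_of_range, what))
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

#' Structural profile: accessible surface area and secondary structure
#'
#' Combines predicted ASA with two three-state secondary-structure
#' probability sets (a standard and a class-balanced predictor), columns
#' ordered H, C, E within each set. Probabilities outside [0, 1] are
#' clipped with a warning.
#'
#' @param asa Numeric vector of per-residue accessible surface area.
#' @param ss_probs L x 3 table with columns `H`, `C`, `E`.
#' @param balanced_ss_probs L x 3 table with columns `H`, `C`, `E`.
#' @return L x 7 tibble: `asa`, `ss_H`, `ss_C`, `ss_E`, `ssb_H`, `ssb_C`,
#'   `ssb_E`.
#' @export
structural_profile <- function(asa, ss_probs, balanced_ss_probs) {
  ss <- as_tibble(ss_probs)[, c("H", "C", "E")]
  ssb <- as_tibble(balanced_ss_probs)[, c("H", "C", "E")]
  L <- length(asa)
  if (nrow(ss) != L || nrow(ssb) != L) {
    abort("`asa`, `ss_probs` and `balanced_ss_probs` must share length")
  }
  tibble(asa = asa,
         ss_H = clip_probs(ss$H, "SS"), ss_C = clip_probs(ss$C, "SS"),
         ss_E = clip_probs(ss$E, "SS"),
         ssb_H = clip_probs(ssb$H, "balanced SS"),
         ssb_C = clip_probs(ssb$C, "balanced SS"),
         ssb_E = clip_probs(ssb$E, "balanced SS"))
}

#' Flexibility profile: disorder, predicted fluctuations and contact energy
#'
#' @param disorder Per-residue disorder probability (clipped to [0, 1] with
#'   a warning if outside).
#' @param pred_dphi,pred_dpsi Predicted normalised torsion-angle
#'   fluctuations from an upstream sequence-based predictor.
#' @param psee Per-residue position-specific estimated energy; may be NULL
#'   (e.g. missing input file) or contain NAs, in which case assembly-time
#'   imputation fills the gaps.
#' @return L x 4 tibble: `disorder`, `dphi_pred`, `dpsi_pred`, `psee`.
#' @export
flexibility_profile <- function(disorder, pred_dphi, pred_dpsi, psee = NULL) {
  L <- length(disorder)
  psee <- psee %||% rep(NA_real_, L)
  if (length(pred_dphi) != L || length(pred_dpsi) != L || length(psee) != L) {
    abort("flexibility inputs must share length")
  }
  tibble(disorder = clip_probs(disorder, "disorder"),
         dphi_pred = pred_dphi, dpsi_pred = pred_dpsi, psee = psee)
}

#' Default feature-group layout
#'
#' Named group widths of the documented default assembly: one-hot residue
#' identity (20), five-factor physicochemical scores (5), normalised PSSM
#' (20), monogram (1), bigram (20), structural profile (7) and flexibility
#' profile (4) -- 77 base columns in total.
#'
#' @return Named integer vector of group widths.
#' @export
default_feature_layout <- function() {
  c(residue = 20L, physiochemical = 5L, pssm = 20L, monogram = 1L,
    bigram = 20L, structural = 7L, flexibility = 4L)
}

#' Assemble per-residue feature blocks into one feature matrix
#'
#' Horizontally concatenates the enabled feature blocks in the given order
#' and attaches per-column group metadata. Remaining NAs (e.g. a missing
#' PSEE input) are imputed with the chain-level column mean, falling back
#' to zero when a column is entirely undefined, so the assembled matrix is
#' NA-free.
#'
#' @param blocks Named list of L-row tibbles (names are group labels), e.g.
#'   the outputs of [residue_profile()], [load_pssm()], [monogram()], ...
#' @param chain_id Chain identifier stored alongside the features.
#' @return Tibble of class `taf_features` with `chain_id`, 0-based
#'   `residue_index`, and one column per feature; the `"feature_groups"`
#'   attribute maps columns to groups.
#' @export
assemble_features <- function(blocks, chain_id = "chain") {
  if (length(blocks) == 0L || is.null(names(blocks))) {
    abort("`blocks` must be a non-empty named list")
  }
  L <- unique(vapply(blocks, nrow, 1L))
  if (length(L) != 1L) abort("all blocks must share the same number of rows")
  groups <- tibble(
    column = unlist(lapply(blocks, names), use.names = FALSE),
    group = rep(names(blocks), vapply(blocks, ncol, 1L)))
  if (anyDuplicated(groups$column)) abort("duplicate feature column names")
  out <- bind_cols(tibble(chain_id = chain_id, residue_index = seq_len(L) - 1L),
                   blocks)
  names(out) <- c("chain_id", "residue_index", groups$column)
  for (cl in groups$column) {
    v <- out[[cl]]
    if (anyNA(v)) {
      fill <- mean(v, na.rm = TRUE)
      v[is.na(v)] <- if (is.nan(fill)) 0 else fill
      out[[cl]] <- v
    }
  }
  new_taf_features(out, groups)
}

new_taf_features <- function(tbl, groups) {
  structure(tbl, feature_groups = groups,
            class = c("taf_features", class(tibble())))
}

#' Column-to-group metadata of a feature matrix
#'
#' @param x A `taf_features` tibble.
#' @return Tibble with columns `column` and `group` (and, after
#'   windowing, `source_column` and `offset`).
#' @export
feature_groups <- function(x) {
  attr(x, "feature_groups", exact = TRUE)
}

feature_columns <- function(x) {
  setdiff(names(x), c("chain_id", "residue_index"))
}

# feature tibble -> plain numeric matrix of the feature columns
feature_matrix <- function(x) {
  as.matrix(as_tibble(x)[, feature_columns(x), drop = FALSE])
}

#' Sliding-window concatenation of a feature matrix
#'
#' Row i of the result concatenates the base feature rows at offsets
#' -(ws-1)/2 ... +(ws-1)/2 around residue i, per chain. Out-of-range
#' offsets are zero-padded by default (or edge-replicated). Window column
#' names carry the offset as a suffix (`_m1`, `_0`, `_p1`, ...).
#'
#' @param x A `taf_features` tibble (possibly several chains).
#' @param ws Odd window size >= 1; `ws = 1` returns the input layout.
#' @param pad `"zero"` (default) or `"edge"`.
#' @return A `taf_features` tibble of width D * ws whose group metadata
#'   records each window column's source column and offset.
#' @export
window_features <- function(x, ws, pad = c("zero", "edge")) {
  pad <- match.arg(pad)
  if (ws < 1L || ws %% 2L == 0L) abort("`ws` must be an odd positive integer")
  h <- (ws - 1L) %/% 2L
  base_groups <- feature_groups(x)
  cols <- feature_columns(x)
  offsets <- seq(-h, h)
  suffix <- ifelse(offsets < 0, paste0("_m", -offsets),
                   ifelse(offsets > 0, paste0("_p", offsets), "_0"))
  shift_chain <- function(df) {
    m <- as.matrix(df[, cols, drop = FALSE])
    Lc <- nrow(m)
    parts <- lapply(seq_along(offsets), function(k) {
      o <- offsets[k]
      src <- seq_len(Lc) + o
      if (pad == "edge") src <- pmin(pmax(src, 1L), Lc)
      ok <- src >= 1L & src <= Lc
      sm <- matrix(0, nrow = Lc, ncol = ncol(m))
      sm[ok, ] <- m[src[ok], , drop = FALSE]
      colnames(sm) <- paste0(cols, suffix[k])
      sm
    })
    bind_cols(df[, c("chain_id", "residue_index")],
              as_tibble(do.call(cbind, parts)))
  }
  out <- as_tibble(x) |>
    dplyr::group_split(.data$chain_id) |>
    lapply(shift_chain) |>
    bind_rows()
  groups <- tibble(
    column = unlist(lapply(suffix, function(s) paste0(cols, s))),
    group = rep(base_groups$group[match(cols, base_groups$column)],
                times = length(offsets)),
    source_column = rep(cols, times = length(offsets)),
    offset = rep(offsets, each = length(cols)))
  new_taf_features(out, groups)
}

#' Read / write a feature matrix as TSV with a JSON metadata sidecar
#'
#' The features go to `<path>`; the column-group metadata goes to
#' `<path>.groups.json` so a later stage can reconstruct the layout.
#'
#' @param x A `taf_features` tibble.
#' @param path TSV path.
#' @return `path` invisibly for the writer; a `taf_features` tibble for the
#'   reader.
#' @export
write_features_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  jsonlite::write_json(feature_groups(x), paste0(path, ".groups.json"),
                       digits = NA)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  gpath <- paste0(path, ".groups.json")
  groups <- if (file.exists(gpath)) {
    as_tibble(jsonlite::read_json(gpath, simplifyVector = TRUE))
  } else {
    tibble(column = setdiff(names(tbl), c("chain_id", "residue_index")),
           group = "unknown")
  }
  new_taf_features(tbl, groups)
}
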