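#' Circular mean of angles
#'
#' Mean direction by unit-vector averaging: atan2 of the mean sine and
#' cosine. Undefined when the resultant vector length is (numerically)
#' zero, e.g. for an antipodal pair.
#'
#' @param angles Numeric vector of angles in degrees.
#' @return Mean direction in degrees in (-180, 180].
#' @examples
#' circular_mean(c(170, -170)) # 180: the naive mean, 0, points the wrong way
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0L || anyNA(angles)) {
    abort("`angles` must be non-empty and free of NA")
  }
  rad <- angles * pi / 180
  s <- mean(sin(rad))
  c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12) {
    abort("circular mean undefined: angles balance out (zero resultant)",
          class = "torsionflux_degenerate_mean")
  }
  wrap_angle(atan2(s, c) * 180 / pi)
}

#' Circular fluctuation (wrapped standard deviation) of angles
#'
#' Dispersion of a set of angles about their circular mean: deviations are
#' wrapped into (-180, 180] and the root mean square taken. With the default
#' population normalisation this is bounded by 180 degrees, which makes the
#' normalised fluctuation label [normalize_fluctuation()] live in [0, 1].
#'
#' @param angles Numeric vector of at least two angles in degrees.
#' @param population If TRUE (default) divide by M; if FALSE divide by M - 1.
#' @return Fluctuation in degrees in [0, 180].
#' @examples
#' circular_fluctuation(c(170, -170)) # mean 180, deviations +-10 -> 10
#' @export
circular_fluctuation <- function(angles, population = TRUE) {
  if (length(angles) < 2L) {
    abort("need at least two angles to measure fluctuation",
          class = "torsionflux_insufficient_data")
  }
  mu <- circular_mean(angles)
  dev <- wrap_angle(angles - mu)
  denom <- if (population) length(angles) else length(angles) - 1L
  sqrt(sum(dev^2) / denom)
}

#' Normalise an angular fluctuation to [0, 1]
#'
#' Divides a fluctuation in degrees by 180, the upper bound of the wrapped
#' standard deviation, putting labels on the dimensionless scale used for
#' training and evaluation.
#'
#' @param sigma Fluctuation in degrees, in [0, 180].
#' @return Dimensionless value in [0, 1].
#' @export
normalize_fluctuation <- function(sigma) {
  if (any(sigma < 0 | sigma > 180, na.rm = TRUE)) {
    abort("`sigma` must lie in [0, 180] degrees")
  }
  sigma / 180
}

#' Per-residue fluctuation labels from an ensemble's dihedrals
#'
#' Reduces the per-model phi/psi series of a chain to one normalised
#' fluctuation pair (dphi, dpsi) per residue: the wrapped standard deviation
#' across models, divided by 180. A residue's label is undefined (NA, with
#' the `*_defined` flag FALSE) wherever fewer than two models define the
#' underlying dihedral; such positions are excluded from training and
#' evaluation rather than imputed.
#'
#' @param dihedrals Tibble from [backbone_dihedrals()] (may hold several
#'   chains).
#' @param population Passed to [circular_fluctuation()].
#' @return Tibble with columns `chain_id`, `residue_index`, `aa`, `dphi`,
#'   `dpsi`, `dphi_defined`, `dpsi_defined`.
#' @export
fluctuation_profile <- function(dihedrals, population = TRUE) {
  m_per_chain <- dihedrals |>
    dplyr::distinct(.data$chain_id, .data$model) |>
    dplyr::count(.data$chain_id)
  if (any(m_per_chain$n < 2L)) {
    abort(sprintf("chains with fewer than 2 models: %s",
                  paste(m_per_chain$chain_id[m_per_chain$n < 2L], collapse = ", ")))
  }
  fluct1 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    tryCatch(normalize_fluctuation(circular_fluctuation(x, population)),
             torsionflux_degenerate_mean = function(e) NA_real_)
  }
  dihedrals |>
    group_by(.data$chain_id, .data$residue_index, .data$aa) |>
    summarise(dphi = fluct1(.data$phi), dpsi = fluct1(.data$psi),
              .groups = "drop") |>
    mutate(dphi_defined = !is.na(.data$dphi),
           dpsi_defined = !is.na(.data$dpsi)) |>
    arrange(.data$chain_id, .data$residue_index)
}

#' Filter an ensemble set by model count, length and residue standardness
#'
#' Keeps chains with at least `min_models` models, at least `min_length`
#' residues, and only standard amino acids. Each rejected chain is
#' attributed to the first rule it fails, with rules checked in that order.
#'
#' @param chains List of [taf_ensemble()] objects.
#' @param min_models Minimum ensemble size (default 5; chains with fewer
#'   models are removed).
#' @param min_length Minimum chain length (default 25).
#' @return Object of class `taf_filter_report`: a list with `kept` (the
#'   surviving ensembles), `survivors` (their ids), `n_input`, and the
#'   per-rule removal counts `removed_models`, `removed_length`,
#'   `removed_nonstandard`.
#' @export
apply_dataset_filters <- function(chains, min_models = 5, min_length = 25) {
  verdict <- vapply(chains, function(e) {
    if (n_models(e) < min_models) return("models")
    if (chain_length(e) < min_length) return("length")
    if (e$nonstandard) return("nonstandard")
    "kept"
  }, "")
  kept <- chains[verdict == "kept"]
  structure(
    list(kept = kept,
         survivors = vapply(kept, function(e) e$chain_id, ""),
         n_input = length(chains),
         removed_models = sum(verdict == "models"),
         removed_length = sum(verdict == "length"),
         removed_nonstandard = sum(verdict == "nonstandard"),
         min_models = min_models, min_length = min_length),
    class = "taf_filter_report")
}

#' @export
print.taf_filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<taf_filter_report> %d chains in, %d kept\n",
    "  removed: %d with < %d models, %d shorter than %d, %d nonstandard\n"),
    x$n_input, length(x$survivors),
    x$removed_models, x$min_models,
    x$removed_length, x$min_length, x$removed_nonstandard))
  invisible(x)
}

#' @method tidy taf_filter_report
#' @export
tidy.taf_filter_report <- function(x, ...) {
  tibble(rule = c("kept", "models", "length", "nonstandard"),
         n = c(length(x$survivors), x$removed_models,
               x$removed_length, x$removed_nonstandard))
}

#' Histogram of fluctuation labels
#'
#' Bins the defined dphi and dpsi labels into `n_bins` equal-width bins on
#' [0, 1]; the last bin is closed on the right so a label of exactly 1 is
#' counted.
#'
#' @param profiles Label tibble from [fluctuation_profile()].
#' @param n_bins Number of bins (default 10).
#' @return Tibble with columns `angle` ("dphi"/"dpsi"), `bin`, `lower`,
#'   `upper`, `count`.
#' @export
fluctuation_histogram <- function(profiles, n_bins = 10) {
  if (n_bins < 1L) abort("`n_bins` must be at least 1")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin1 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(integer(n_bins))
    b <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = FALSE)
    tabulate(b, nbins = n_bins)
  }
  tibble(angle = rep(c("dphi", "dpsi"), each = n_bins),
         bin = rep(seq_len(n_bins), 2L),
         lower = rep(head(breaks, -1L), 2L),
         upper = rep(tail(breaks, -1L), 2L),
         count = c(bin1(profiles$dphi), bin1(profiles$dpsi)))
}

#' Correlation between dphi and dpsi labels
#'
#' Pearson correlation of the two fluctuation labels over residues where
#' both are defined. Neighbouring backbone torsions share a chemical-bond
#' linkage, so real ensembles show a clear positive association.
#'
#' @param profiles Label tibble from [fluctuation_profile()].
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
dphi_dpsi_correlation <- function(profiles) {
  ok <- profiles$dphi_defined & profiles$dpsi_defined
  if (sum(ok) < 2L) abort("need at least two residues with both labels defined")
  pcc(profiles$dphi[ok], profiles$dpsi[ok])
}

#' Write / read fluctuation labels as TSV
#'
#' Plain tab-separated persistence of the label table (one row per residue,
#' 0-based `residue_index`, NA for undefined labels).
#'
#' @param profiles Label tibble from [fluctuation_profile()].
#' @param path File path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_labels_tsv <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chain_id = readr::col_character(),
                    residue_index = readr::col_integer(),
                    aa = readr::col_character(),
                    dphi = readr::col_double(),
                    dpsi = readr::col_double(),
                    dphi_defined = readr::col_logical(),
                    dpsi_defined = readr::col_logical()))
}

#' Fluctuation distribution plot
#'
#' Bar plot of the binned dphi/dpsi label distribution.
#'
#' @param profiles Label tibble from [fluctuation_profile()].
#' @param n_bins Number of bins.
#' @return A ggplot object.
#' @export
plot_fluctuation_distribution <- function(profiles, n_bins = 10) {
  h <- fluctuation_histogram(profiles, n_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                  y = .data$count, fill = .data$angle)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "normalised torsion-angle fluctuation", y = "residues",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
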