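#' Published benchmark metrics for torsion-fluctuation predictors
#'
#' Cross-validated MAE and PCC reported for sequence-based backbone
#' torsion-angle fluctuation predictors on a common NMR-derived dataset:
#' the earlier neural-network baseline (`baseline_nn`, whose MAEs were
#' also reported on the degree scale, column `mae_deg`) and the tuned
#' gradient-boosted model with window-3 features and GA-selected columns
#' (`gbt_selected`, with its printed percentage improvements over the
#' baseline). Used in documentation examples and internal consistency
#' checks -- e.g. `mae_deg / 180` reproduces the dimensionless `mae`, and
#' averaging the printed improvement pair reproduces the printed average.
#'
#' @return Tibble with columns `angle`, `method`, `mae`, `pcc`, `mae_deg`,
#'   `mae_improvement`, `pcc_improvement`, `average_improvement`.
#' @export
reference_benchmarks <- function() {
  path <- system.file("extdata", "benchmark_reference.tsv",
                      package = "torsionflux", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
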