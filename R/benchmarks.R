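# Published benchmark results shipped with the package as plain TSV tables.
# These are reference numbers for the detector family this package
# re-implements; the test suite uses them for arithmetic-consistency checks
# (reported improvements must be recomputable from the tables).

#' Load a shipped benchmark table
#'
#' Available tables: `chickenflow` (full test set), `chickenflow_dense`
#' (dense-occlusion subset: OR > 0.5, objects > 40), `goosedetect`,
#' `sheepcounter`, `lshead_middle_channel`, `component_ablation`,
#' `dataset_counts`.
#'
#' @param name Table name (file stem under `extdata/benchmarks`).
#' @return Data frame.
#' @export
benchmark_table <- function(name) {
  path <- system.file("extdata", "benchmarks", paste0(name, ".tsv"),
                      package = "sddetect")
  if (!nzchar(path)) stop("unknown benchmark table: ", name)
  utils::read.delim(path, check.names = FALSE)
}
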