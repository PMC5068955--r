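#' Load a packaged fixture table
#'
#' Verbatim transcriptions of the published summary tables shipped with
#' the package: "table1" (module sizes, eigengene variance explained and
#' cross-species consistency), "table2" (pathway enrichment of the
#' preserved modules) and "table3"/"table4"/"table5" (per-gene dosage
#' association statistics of three trans-acting SNPs against the 28
#' oxidative-phosphorylation genes). "table_snps" carries the three SNPs'
#' metadata (locus, MAF, imputation quality).
#'
#' @param name one of "table1".."table5", "table_snps".
#' @return data.frame with the printed column names (values as printed;
#'   numeric columns parse exactly).
#' @export
fixture_table <- function(name = c("table1", "table2", "table3", "table4",
                                   "table5", "table_snps")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "presnet")
  if (!nzchar(path)) stop("fixture not found: ", name)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

fixture_numeric_column <- function(t, column) {
  if (!column %in% names(t)) stop("unknown column: ", column)
  v <- suppressWarnings(as.numeric(t[[column]]))
  if (all(is.na(v))) stop("column is not numeric: ", column)
  v
}

#' Exact summary of a numeric fixture column
#'
#' For the module table, the unassigned-gene row (module "M0") is
#' excluded unless requested, mirroring the published convention of
#' summarizing the 27 modules only.
#'
#' @param t a fixture table (or any data.frame).
#' @param column column name as printed (e.g. "Size", "% Consistent
#'   Genes").
#' @param stat one of "min", "max", "mean", "sum".
#' @param include_unassigned keep an "M0" row if present (default FALSE).
#' @return a single number.
#' @export
table_column_summary <- function(t, column,
                                 stat = c("min", "max", "mean", "sum"),
                                 include_unassigned = FALSE) {
  stat <- match.arg(stat)
  if (!include_unassigned && names(t)[1L] %in% c("Modules", "Module")) {
    t <- t[t[[1L]] != "M0", , drop = FALSE]
  }
  v <- fixture_numeric_column(t, column)
  switch(stat, min = min(v), max = max(v), mean = mean(v), sum = sum(v))
}

#' Count rows with a column strictly below a threshold
#'
#' Strict "<": a value printed exactly at the threshold is not counted.
#'
#' @param t a fixture table.
#' @param column numeric column name.
#' @param threshold numeric threshold.
#' @return integer count.
#' @export
count_below <- function(t, column, threshold) {
  v <- fixture_numeric_column(t, column)
  sum(v < threshold)
}
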