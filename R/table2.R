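#' Packaged top-20 weight-score table
#'
#' The published top-20 gene table of the in vivo liver study, transcribed
#' verbatim: for each probe set, the eight raw parameter values
#' (specificity, average ratio, positive condition, positive chemical,
#' t-test p-value, basal log10 expression, reverse change, control CV%),
#' the corresponding 0-5 component scores, the weighted total and the gene
#' symbol. This fixture anchors the scoring implementation: the shipped
#' default score-bin tables are inferred from its 160 (value, score) pairs,
#' and the weighted-total formula must reproduce its printed totals exactly.
#'
#' @return data frame of 20 rows with columns `probe_id`, the eight
#'   `<parameter>` / `<parameter>_score` pairs, `total_score`, `symbol`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_weight_scores.tsv",
                      package = "gtxscore", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(probe_id = "character", symbol = "character"))
}

#' Names of the eight scored parameters, in weight-formula order
#' @return character vector of length 8.
#' @export
score_parameters <- function() {
  c("specificity", "ave_ratio", "positive_condition", "positive_chemical",
    "p_value", "basal", "reverse_change", "cv_percent")
}

#' Weights of the eight component scores in the total
#' @return named numeric vector of length 8 (total attainable 37.5).
#' @export
score_weights <- function() {
  stats::setNames(c(2, 1, 1, 1, 1, 0.5, 0.5, 0.5), score_parameters())
}
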