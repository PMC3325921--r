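#' Weighted total score from the eight component scores
#'
#' `total = 2*S_specificity + S_ave_ratio + S_positive_condition +
#' S_positive_chemical + S_p_value + 0.5*S_basal + 0.5*S_reverse_change +
#' 0.5*S_cv`. Specificity carries double weight and the three
#' robustness-flavoured components half weight; with all components at 5 the
#' maximum attainable total is 37.5.
#'
#' @param scores numeric vector (or matrix / data frame with one column per
#'   component, rows = genes) of component scores in 0..5, ordered as
#'   [score_parameters()]; names, when present, are checked.
#' @return numeric total(s).
#' @export
total_score <- function(scores) {
  w <- score_weights()
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.matrix(scores)) {
    if (ncol(scores) != 8L) stop("need all 8 component scores")
    if (!is.null(colnames(scores)) && !identical(colnames(scores), names(w))) {
      scores <- scores[, names(w), drop = FALSE]
    }
    bad <- !is.finite(scores) | scores < 0 | scores > 5
  } else {
    if (length(scores) != 8L) stop("need all 8 component scores")
    if (!is.null(names(scores)) && !identical(names(scores), names(w))) {
      scores <- scores[names(w)]
    }
    bad <- !is.finite(scores) | scores < 0 | scores > 5
    scores <- matrix(scores, nrow = 1L)
  }
  if (any(bad)) stop("component scores must all be present and in 0..5")
  as.vector(scores %*% w)
}

#' Score and rank genes of a called dataset
#'
#' The end of the discovery pipeline: computes the eight parameters per gene
#' ([gene_parameters()]), bins each into a 0-5 component score, combines
#' them into the weighted total and ranks genes by it. Only genes with at
#' least one GTX up-call are scorable (specificity and average ratio are
#' undefined otherwise); the remainder are excluded, not scored 0. Ties in
#' the total are broken by higher specificity, then higher average ratio,
#' then gene id, so the ranking is deterministic.
#'
#' @param calls a called `call_matrix`.
#' @param dataset the originating `gtx_dataset` (raw intensities; for basal
#'   and CV over control animals).
#' @param bin_tables named list of `score_bin_table`s; default
#'   [default_bin_tables()].
#' @param pooled_t,basal_of_means passed to [gene_parameters()].
#' @return data frame, one row per scored gene in rank order: `gene_id`,
#'   `rank`, the eight raw parameter columns, the eight `<parameter>_score`
#'   columns and `total_score`.
#' @export
score_genes <- function(calls, dataset, bin_tables = default_bin_tables(),
                        pooled_t = FALSE, basal_of_means = TRUE) {
  par <- gene_parameters(calls, dataset, pooled_t = pooled_t,
                         basal_of_means = basal_of_means)
  keep <- !is.na(par$specificity) & !is.na(par$ave_ratio)
  par <- par[keep, , drop = FALSE]
  if (nrow(par) == 0L) {
    out <- cbind(par[, "gene_id", drop = FALSE], rank = integer(0), par[, -1L],
                 total_score = numeric(0))
    return(out)
  }
  smat <- vapply(score_parameters(), function(p) {
    bin_score(par[[p]], bin_tables[[p]])
  }, integer(nrow(par)))
  if (nrow(par) == 1L) smat <- matrix(smat, nrow = 1L,
                                      dimnames = list(NULL, score_parameters()))
  total <- total_score(smat)
  ord <- order(-total, -par$specificity, -par$ave_ratio, par$gene_id)
  out <- data.frame(par[ord, , drop = FALSE],
                    smat[ord, , drop = FALSE],
                    total_score = total[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[10:17] <- paste0(score_parameters(), "_score")
  out <- cbind(out[, "gene_id", drop = FALSE], rank = seq_len(nrow(out)),
               out[, -1L, drop = FALSE])
  out
}

#' One-call discovery pipeline on a raw dataset
#'
#' Per-chip normalization, treated/control ratios, step-wise regulation
#' calls, parameter computation, binning, weighting and ranking.
#'
#' @param dataset a raw `gtx_dataset`.
#' @param criteria [call_criteria()]; default [default_call_criteria()].
#' @param bin_tables default [default_bin_tables()].
#' @param ... passed to [score_genes()].
#' @return list with `calls` (the called `call_matrix`) and `scores` (the
#'   ranked score table of [score_genes()]).
#' @export
rank_genes <- function(dataset, criteria = default_call_criteria(),
                       bin_tables = default_bin_tables(), ...) {
  chip <- normalize_per_chip(dataset)
  calls <- call_regulation(compute_ratios(chip), criteria)
  scores <- score_genes(calls, dataset, bin_tables = bin_tables, ...)
  list(calls = calls, scores = scores)
}

#' Write a ranked score table as TSV
#'
#' @param scores score table from [score_genes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
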