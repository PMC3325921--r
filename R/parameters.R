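#' Per-gene scoring parameters
#'
#' The eight per-gene parameters that feed the weighted biomarker score.
#' Counting conventions: "pink cells" are up-calls and "blue cells"
#' down-calls in the gene x condition call matrix; cell counts for
#' specificity, positive chemical and reverse change are unweighted, while
#' positive condition uses the per-cell replication weight (0.5 for each cell
#' of a duplicated chemical) so a duplicated chemical is not double-counted.
#'
#' @name gene-parameters
#' @param call character vector of calls (`"up"`/`"down"`/`"none"`) over the
#'   gene's conditions.
#' @param ratio numeric vector of treated/control ratios over conditions.
#' @param class character vector, `"GTX"`/`"NGTX"` per condition.
#' @param chemical character vector of chemical names per condition.
#' @param weight numeric per-condition replication weights.
#' @param x numeric vector of control-animal intensities.
NULL

#' @describeIn gene-parameters Fraction of a gene's up-calls that fall in
#'   GTX conditions (1 means perfectly genotoxin-specific). `NA` when the
#'   gene has no up-call at all: such genes are excluded from scoring, which
#'   is distinct from a specificity of 0.
#' @export
specificity <- function(call, class) {
  up <- call == "up"
  if (!any(up)) return(NA_real_)
  sum(up & class == "GTX") / sum(up)
}

#' @describeIn gene-parameters Unweighted mean ratio over the gene's GTX
#'   up-calls; `NA` (excluded) when there is none.
#' @export
ave_ratio <- function(call, ratio, class) {
  sel <- call == "up" & class == "GTX"
  if (!any(sel)) return(NA_real_)
  mean(ratio[sel])
}

#' @describeIn gene-parameters Weighted count of GTX up-calls; each cell
#'   contributes its replication weight, so a chemical hybridized in
#'   duplicate contributes 0.5 per cell.
#' @export
positive_condition <- function(call, class, weight) {
  sum(weight[call == "up" & class == "GTX"])
}

#' @describeIn gene-parameters Number of distinct GTX chemicals with at
#'   least one up-call (a duplicated chemical counts once).
#' @export
positive_chemical <- function(call, class, chemical) {
  length(unique(chemical[call == "up" & class == "GTX"]))
}

#' Welch t-test p-value between GTX and NGTX condition intensities
#'
#' Two-sided two-sample t-test comparing a gene's per-condition normalized
#' intensities between genotoxin and non-genotoxin conditions. Welch
#' (unequal-variance) by default; a pooled-variance flavour is available.
#' When both groups are constant, the p-value is 1 if their means are equal
#' and 0 otherwise, by convention.
#'
#' @param gtx,ngtx numeric vectors of per-condition values (each length >= 2).
#' @param pooled logical; use the pooled-variance (Student) statistic.
#' @return p-value in \[0, 1\].
#' @export
group_p_value <- function(gtx, ngtx, pooled = FALSE) {
  n1 <- length(gtx); n2 <- length(ngtx)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  m1 <- mean(gtx); m2 <- mean(ngtx)
  v1 <- stats::var(gtx); v2 <- stats::var(ngtx)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se2 == 0 || !is.finite(df)) return(if (m1 == m2) 1 else 0)
  tstat <- (m1 - m2) / sqrt(se2)
  2 * stats::pt(-abs(tstat), df)
}

#' @describeIn gene-parameters Basal expression: log10 of the mean signal
#'   intensity over control animals (with `of_means = FALSE`, the mean of
#'   per-animal log10 intensities instead).
#' @param of_means logical; `TRUE` (default) takes log10 of the mean.
#' @export
basal_expression <- function(x, of_means = TRUE) {
  if (any(x <= 0)) stop("control intensities must be positive")
  if (of_means) log10(mean(x)) else mean(log10(x))
}

#' @describeIn gene-parameters Reverse change: down-calls in NGTX minus
#'   down-calls in GTX conditions; positive values mean the gene moves in
#'   the genotoxin-specific direction.
#' @export
reverse_change <- function(call, class) {
  dn <- call == "down"
  sum(dn & class == "NGTX") - sum(dn & class == "GTX")
}

#' @describeIn gene-parameters Coefficient of variation (percent),
#'   100 x sample SD / mean, of control-animal intensities.
#' @export
cv_percent <- function(x) {
  if (length(x) < 2L) stop("CV needs at least 2 control animals")
  m <- mean(x)
  if (m <= 0) stop("CV undefined: mean control intensity is not positive")
  100 * stats::sd(x) / m
}

#' Compute all eight scoring parameters for every gene
#'
#' Vectorized over genes. Basal expression and CV% are computed from the
#' control-animal intensities of the supplied dataset (raw scanner scale);
#' the t-test compares each gene's per-condition ratios between GTX and NGTX
#' conditions.
#'
#' @param calls a called `call_matrix` (see [call_regulation()]).
#' @param dataset the `gtx_dataset` the calls came from (raw intensities;
#'   used for basal and CV over all control animals).
#' @param pooled_t logical, pooled-variance t-test instead of Welch.
#' @param basal_of_means see [basal_expression()].
#' @return data frame: `gene_id` plus the eight parameter columns named as
#'   [score_parameters()]. Genes with no up-call anywhere have `NA`
#'   specificity; genes with no GTX up-call have `NA` ave_ratio.
#' @export
gene_parameters <- function(calls, dataset, pooled_t = FALSE,
                            basal_of_means = TRUE) {
  cl <- calls$call
  R <- calls$ratio
  cond <- calls$conditions
  gtx <- cond$class == "GTX"
  ngtx <- cond$class == "NGTX"
  up <- cl == "up"
  dn <- cl == "down"

  n_up_all <- rowSums(up)
  n_up_gtx <- rowSums(up[, gtx, drop = FALSE])
  spec <- ifelse(n_up_all > 0, n_up_gtx / n_up_all, NA_real_)

  rg <- R[, gtx, drop = FALSE] * up[, gtx, drop = FALSE]
  aver <- ifelse(n_up_gtx > 0, rowSums(rg) / n_up_gtx, NA_real_)

  pos_cond <- as.vector(up[, gtx, drop = FALSE] %*% cond$weight[gtx])

  chems <- unique(cond$chemical[gtx])
  pos_chem <- rowSums(vapply(chems, function(ch) {
    rowSums(up[, gtx & cond$chemical == ch, drop = FALSE]) > 0
  }, logical(nrow(up))))

  pvals <- welch_rows(R[, gtx, drop = FALSE], R[, ngtx, drop = FALSE],
                      pooled = pooled_t)

  ctl <- dataset$samples$role == "control"
  X <- dataset$intensities[, ctl, drop = FALSE]
  m <- rowMeans(X)
  if (any(m <= 0)) stop("basal/CV undefined: non-positive control mean")
  basal <- if (basal_of_means) log10(m) else rowMeans(log10(X))
  sdv <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1L))
  cv <- 100 * sdv / m

  rev <- rowSums(dn[, ngtx, drop = FALSE]) - rowSums(dn[, gtx, drop = FALSE])

  data.frame(gene_id = rownames(cl), specificity = spec, ave_ratio = aver,
             positive_condition = pos_cond, positive_chemical = pos_chem,
             p_value = pvals, basal = basal, reverse_change = rev,
             cv_percent = cv, row.names = NULL, stringsAsFactors = FALSE)
}

# Row-wise two-sample t-test p-values (Welch or pooled); the row-wise analog
# of group_p_value(), with the same zero-variance convention.
welch_rows <- function(A, B, pooled = FALSE) {
  n1 <- ncol(A); n2 <- ncol(B)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 conditions")
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1L)
  v2 <- rowSums((B - m2)^2) / (n2 - 1L)
  if (pooled) {
    se2 <- (((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs((m1 - m2) / sqrt(se2)), df)
  degenerate <- se2 == 0 | !is.finite(df)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}
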