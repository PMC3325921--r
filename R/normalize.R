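#' Two-step normalization of an expression dataset
#'
#' Per-chip: every sample is scaled so that its median intensity is 1,
#' removing array-to-array brightness differences. Per-gene: every value is
#' divided by the median of the gene's matched control samples (controls with
#' the same solvent and timepoint), so each gene is expressed relative to its
#' solvent-control level. `normalize_per_chip()` applies the first step only;
#' `normalize()` applies both. Gene and sample order are preserved.
#'
#' Note the per-gene step cancels in downstream treated/control ratios (both
#' numerator and denominator are divided by the same control median), so
#' [compute_ratios()] yields identical ratios on a per-chip-normalized or a
#' fully normalized dataset; the two differ only in the intensity scale
#' carried along for the intensity-dependent calling bands.
#'
#' @param dataset a `gtx_dataset` (see [generate_dataset()], [read_dataset()]).
#' @return A `gtx_dataset` with normalized intensities.
#' @export
normalize <- function(dataset) {
  dataset <- normalize_per_chip(dataset)
  x <- dataset$intensities
  s <- dataset$samples
  for (grp in split(seq_len(nrow(s)), list(s$solvent, s$timepoint), drop = TRUE)) {
    ctl <- grp[s$role[grp] == "control"]
    if (length(ctl) == 0L) {
      stop("no control samples for solvent/timepoint group of sample ",
           s$sample_id[grp[1L]])
    }
    ref <- apply(x[, ctl, drop = FALSE], 1L, stats::median)
    if (any(ref <= 0)) {
      stop("per-gene normalization undefined: non-positive control median for ",
           sum(ref <= 0), " gene(s)")
    }
    x[, grp] <- x[, grp, drop = FALSE] / ref
  }
  dataset$intensities <- x
  dataset
}

#' @rdname normalize
#' @export
normalize_per_chip <- function(dataset) {
  x <- dataset$intensities
  if (any(x < 0)) stop("intensities must be non-negative")
  med <- apply(x, 2L, stats::median)
  if (any(med <= 0)) {
    bad <- colnames(x)[med <= 0][1L]
    stop("per-chip scaling undefined for sample '", bad,
         "': median intensity is not positive")
  }
  dataset$intensities <- sweep(x, 2L, med, "/")
  dataset
}

#' Treated/control expression ratios per gene and condition
#'
#' For every treatment condition (one chemical cell x timepoint sample) the
#' ratio of its intensity to the mean intensity of the matched control
#' samples (same solvent and timepoint) is computed per gene, together with
#' the control-side mean intensity used later to choose the calling band.
#'
#' @param dataset a normalized `gtx_dataset` (per-chip at least; see
#'   [normalize()]).
#' @return A `call_matrix` object: list with `ratio` and `control_intensity`
#'   (gene x condition matrices), `call` (character matrix, all `"none"`),
#'   and `conditions` (data frame: `condition`, `chemical`, `class`,
#'   `timepoint`, `weight`).
#' @export
compute_ratios <- function(dataset) {
  x <- dataset$intensities
  s <- dataset$samples
  trt <- which(s$role == "treatment")
  if (length(trt) == 0L) stop("dataset has no treatment samples")
  ratio <- matrix(NA_real_, nrow(x), length(trt),
                  dimnames = list(rownames(x), s$sample_id[trt]))
  ctrl_int <- ratio
  for (j in seq_along(trt)) {
    i <- trt[j]
    ctl <- which(s$role == "control" & s$solvent == s$solvent[i] &
                   s$timepoint == s$timepoint[i])
    if (length(ctl) == 0L) {
      stop("no matched controls for treatment sample '", s$sample_id[i], "'")
    }
    ref <- rowMeans(x[, ctl, drop = FALSE])
    if (any(ref <= 0)) {
      stop("ratio undefined: zero control mean for gene '",
           rownames(x)[which(ref <= 0)[1L]], "'")
    }
    ratio[, j] <- x[, i] / ref
    ctrl_int[, j] <- ref
  }
  structure(
    list(ratio = ratio, control_intensity = ctrl_int,
         call = matrix("none", nrow(ratio), ncol(ratio), dimnames = dimnames(ratio)),
         conditions = data.frame(condition = s$sample_id[trt],
                                 chemical = s$chemical[trt], class = s$class[trt],
                                 timepoint = s$timepoint[trt],
                                 weight = s$weight[trt], stringsAsFactors = FALSE)),
    class = "call_matrix"
  )
}

#' @export
print.call_matrix <- function(x, ...) {
  cat("call_matrix:", nrow(x$ratio), "genes x", ncol(x$ratio), "conditions\n")
  tab <- table(factor(x$call, levels = c("up", "down", "none")))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a call matrix as a long-format TSV
#'
#' One row per gene x condition with the ratio, the call and the condition
#' weight, mirroring the colour-coded per-cell layout of the study's scoring
#' spreadsheet.
#'
#' @param calls a `call_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  long <- data.frame(
    gene_id = rep(rownames(calls$ratio), times = ncol(calls$ratio)),
    condition = rep(colnames(calls$ratio), each = nrow(calls$ratio)),
    ratio = as.vector(calls$ratio),
    call = as.vector(calls$call),
    weight = rep(calls$conditions$weight, each = nrow(calls$ratio)),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
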