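#' Generate a synthetic expression dataset with known ground truth
#'
#' Emulates the structure of a pooled-hybridization in vivo study: one
#' treatment intensity vector per (chemical cell, timepoint) condition (the
#' pooled RNA of one treatment group), plus `n_control_animals` individual
#' solvent-control vectors per (solvent, timepoint). Intensities are
#' log-normal: each gene gets a baseline drawn on the log10 scale, control
#' animals vary around it with a log-sd chosen so their natural-scale CV
#' matches `control_cv_percent`, and treatment samples add multiplicative
#' noise (`noise_sd`, natural-log scale). Responsive genes are induced in GTX
#' conditions and confounder genes in NGTX conditions, with per gene x
#' condition log2 fold changes drawn from the requested distribution.
#'
#' @param design a [study_design()].
#' @param effects an [effect_spec()]. Gene ids in the effect spec must exist
#'   in the generated gene list (`g00001 ... gNNNNN`) or be given as integer
#'   indices coercible from the id.
#' @param seed integer seed; mandatory, the run is reproducible bit-for-bit.
#'
#' @return An object of class `gtx_dataset`: a list with
#'   \describe{
#'     \item{intensities}{numeric gene x sample matrix (non-negative), row
#'       names are gene ids, column names sample ids.}
#'     \item{samples}{data frame: `sample_id`, `chemical`, `class`
#'       (`GTX`/`NGTX`/`control`), `timepoint`, `role`
#'       (`treatment`/`control`), `solvent`, `weight`, `replicate`.}
#'     \item{truth}{data frame `gene_id`, `label` in
#'       `responsive`/`confounder`/`null`.}
#'   }
#' @export
generate_dataset <- function(design, effects, seed) {
  if (!inherits(design, "study_design")) stop("`design` must be a study_design")
  if (!inherits(effects, "effect_spec")) stop("`effects` must be an effect_spec")
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("`seed` is required: synthetic datasets must be reproducible")
  }

  gene_ids <- sprintf("g%05d", seq_len(design$n_genes))
  resolve <- function(ids, what) {
    bad <- setdiff(ids, gene_ids)
    if (length(bad) > 0L) {
      stop(what, " gene id(s) not in the design's gene list: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    match(ids, gene_ids)
  }
  idx_resp <- resolve(effects$responsive_gene_ids, "responsive")
  idx_conf <- resolve(effects$ngtx_confounder_gene_ids, "confounder")

  samples <- build_sample_table(design)
  n_genes <- design$n_genes
  n_samples <- nrow(samples)

  # log-sd reproducing a natural-scale CV for log-normal noise
  cv <- effects$control_cv_percent / 100
  sigma_ctrl <- sqrt(log1p(cv^2))

  withr::with_seed(as.integer(seed), {
    baseline <- 10^stats::rnorm(n_genes, effects$baseline_log_intensity[1L],
                                effects$baseline_log_intensity[2L])
    log_x <- matrix(0, n_genes, n_samples)
    is_ctrl <- samples$role == "control"
    n_ctrl <- sum(is_ctrl)
    n_trt <- n_samples - n_ctrl
    if (sigma_ctrl > 0) {
      log_x[, is_ctrl] <- stats::rnorm(n_genes * n_ctrl, 0, sigma_ctrl)
    }
    if (effects$noise_sd > 0) {
      log_x[, !is_ctrl] <- stats::rnorm(n_genes * n_trt, 0, effects$noise_sd)
    }
    trt_gtx <- which(!is_ctrl & samples$class == "GTX")
    trt_ngtx <- which(!is_ctrl & samples$class == "NGTX")
    draw_fc <- function(n, fc) stats::rnorm(n, fc[1L], fc[2L])
    if (length(idx_resp) > 0L && length(trt_gtx) > 0L) {
      log_x[idx_resp, trt_gtx] <- log_x[idx_resp, trt_gtx] +
        log(2) * draw_fc(length(idx_resp) * length(trt_gtx), effects$fold_change)
    }
    if (length(idx_conf) > 0L && length(trt_ngtx) > 0L) {
      log_x[idx_conf, trt_ngtx] <- log_x[idx_conf, trt_ngtx] +
        log(2) * draw_fc(length(idx_conf) * length(trt_ngtx),
                         effects$confounder_fold_change)
    }
    intensities <- baseline * exp(log_x)
  })
  dimnames(intensities) <- list(gene_ids, samples$sample_id)

  label <- rep("null", n_genes)
  label[idx_resp] <- "responsive"
  label[idx_conf] <- "confounder"

  structure(
    list(intensities = intensities, samples = samples,
         truth = data.frame(gene_id = gene_ids, label = label,
                            stringsAsFactors = FALSE)),
    class = "gtx_dataset"
  )
}

# One treatment sample per (chemical cell, timepoint); individual controls
# per (solvent, timepoint).
build_sample_table <- function(design) {
  ch <- design$chemicals
  dup <- ch$name %in% ch$name[duplicated(ch$name)]
  cell <- ifelse(dup, sprintf("%s.%d", ch$name, ch$replicate), ch$name)
  trt <- do.call(rbind, lapply(design$timepoints, function(tp) {
    data.frame(
      sample_id = sprintf("%s_%s", cell, tp),
      chemical = ch$name, class = ch$class, timepoint = tp,
      role = "treatment", solvent = ch$solvent, weight = ch$weight,
      replicate = ch$replicate, stringsAsFactors = FALSE)
  }))
  solvents <- unique(ch$solvent)
  ctl <- expand.grid(animal = seq_len(design$n_control_animals),
                     timepoint = design$timepoints, solvent = solvents,
                     stringsAsFactors = FALSE)
  ctl <- data.frame(
    sample_id = sprintf("ctrl_%s_%s_a%d", ctl$solvent, ctl$timepoint, ctl$animal),
    chemical = "control", class = "control", timepoint = ctl$timepoint,
    role = "control", solvent = ctl$solvent, weight = 1,
    replicate = ctl$animal, stringsAsFactors = FALSE)
  out <- rbind(trt, ctl)
  rownames(out) <- NULL
  out
}

#' @export
print.gtx_dataset <- function(x, ...) {
  cat("gtx_dataset:", nrow(x$intensities), "genes x",
      ncol(x$intensities), "samples\n")
  cat("  treatment conditions:", sum(x$samples$role == "treatment"),
      " control animals:", sum(x$samples$role == "control"), "\n")
  tab <- table(x$truth$label)
  cat("  truth:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a synthetic dataset as plain TSV files
#'
#' Writes `intensities.tsv` (first column `gene_id`), `samples.tsv` and
#' `truth.tsv` into `dir`.
#'
#' @param dataset a `gtx_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `gtx_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ints <- data.frame(gene_id = rownames(dataset$intensities),
                     dataset$intensities, check.names = FALSE)
  utils::write.table(ints, file.path(dir, "intensities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth)) {
    utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ints <- utils::read.delim(file.path(dir, "intensities.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(ints[, -1L, drop = FALSE])
  rownames(m) <- ints$gene_id
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  structure(list(intensities = m, samples = samples, truth = truth),
            class = "gtx_dataset")
}
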