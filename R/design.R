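#' Study design for a multi-chemical, multi-timepoint expression study
#'
#' Describes the treatment arms of an in vivo genotoxicity expression study:
#' a panel of chemicals classified as genotoxin (`GTX`) or non-genotoxin
#' (`NGTX`), the sampling timepoints, and the number of individual
#' solvent-control animals per solvent and timepoint. Each row of `chemicals`
#' is one treatment *column* of the design; a chemical hybridized in duplicate
#' appears as two rows sharing a `name`, each carrying the fractional
#' `weight` used when counting positive conditions.
#'
#' @param chemicals data frame with columns `name` (character), `class`
#'   (`"GTX"` or `"NGTX"`), `solvent` (e.g. `"saline"`, `"corn-oil"`),
#'   `weight` (positive; `0.5` for each cell of a duplicated chemical) and
#'   `replicate` (integer, distinguishes duplicated cells). Defaults to the
#'   ten-compound liver panel of [default_chemicals()].
#' @param timepoints character vector of timepoint labels.
#' @param n_control_animals integer, individual control animals per
#'   (solvent, timepoint) cell. Controls are individual (not pooled) so that
#'   control-animal CV and basal expression are estimable.
#' @param n_genes integer, number of genes (probe sets) to simulate.
#'
#' @return An object of class `study_design`.
#' @seealso [generate_dataset()], [effect_spec()]
#' @export
study_design <- function(chemicals = default_chemicals(),
                         timepoints = c("4h", "20h", "2w", "4w"),
                         n_control_animals = 8L,
                         n_genes = 10000L) {
  chemicals <- as.data.frame(chemicals, stringsAsFactors = FALSE)
  required <- c("name", "class", "solvent", "weight", "replicate")
  missing_cols <- setdiff(required, names(chemicals))
  if (length(missing_cols) > 0L) {
    stop("`chemicals` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(chemicals$class %in% c("GTX", "NGTX"))) {
    stop("chemical class must be 'GTX' or 'NGTX'")
  }
  if (!any(chemicals$class == "GTX") || !any(chemicals$class == "NGTX")) {
    stop("the design needs at least one GTX and one NGTX chemical")
  }
  if (any(!is.finite(chemicals$weight)) || any(chemicals$weight <= 0)) {
    stop("replication weights must be positive")
  }
  if (anyDuplicated(chemicals[, c("name", "replicate")])) {
    stop("duplicated (name, replicate) rows in `chemicals`")
  }
  cls <- tapply(chemicals$class, chemicals$name, function(x) length(unique(x)))
  if (any(cls > 1L)) stop("a chemical cannot be both GTX and NGTX")
  if (length(timepoints) < 1L || anyDuplicated(timepoints)) {
    stop("timepoints must be a non-empty set of unique labels")
  }
  n_control_animals <- as.integer(n_control_animals)
  n_genes <- as.integer(n_genes)
  if (n_control_animals < 1L) stop("n_control_animals must be >= 1")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  structure(
    list(chemicals = chemicals, timepoints = as.character(timepoints),
         n_control_animals = n_control_animals, n_genes = n_genes),
    class = "study_design"
  )
}

#' Default ten-compound chemical panel
#'
#' Seven genotoxins (one of them, DEN, hybridized in duplicate with each cell
#' weighted 0.5) and three non-genotoxins, each dissolved in corn oil or
#' saline. Nitrosamines and ENU are saline-soluble; the polycyclic compounds
#' and DEHP require corn oil.
#'
#' @return data frame suitable for the `chemicals` argument of
#'   [study_design()].
#' @export
default_chemicals <- function() {
  ch <- rbind(
    data.frame(name = "DMN",  class = "GTX",  solvent = "saline"),
    data.frame(name = "DEN",  class = "GTX",  solvent = "saline"),
    data.frame(name = "DEN",  class = "GTX",  solvent = "saline"),
    data.frame(name = "ENU",  class = "GTX",  solvent = "saline"),
    data.frame(name = "DPN",  class = "GTX",  solvent = "saline"),
    data.frame(name = "AAT",  class = "GTX",  solvent = "corn-oil"),
    data.frame(name = "DBP",  class = "GTX",  solvent = "corn-oil"),
    data.frame(name = "DMBA", class = "GTX",  solvent = "corn-oil"),
    data.frame(name = "EtOH", class = "NGTX", solvent = "saline"),
    data.frame(name = "PB",   class = "NGTX", solvent = "saline"),
    data.frame(name = "DEHP", class = "NGTX", solvent = "corn-oil")
  )
  ch$replicate <- stats::ave(seq_len(nrow(ch)), ch$name, FUN = seq_along)
  dup <- ch$name %in% ch$name[duplicated(ch$name)]
  ch$weight <- ifelse(dup, 0.5, 1)
  ch[, c("name", "class", "solvent", "weight", "replicate")]
}

#' Effect specification for the synthetic-data generator
#'
#' Defines which genes respond, and how strongly, in the simulated study.
#' Responsive genes are induced in every GTX treatment cell; confounder genes
#' are induced in NGTX cells only (they emulate non-genotoxic stress
#' responders that the scoring should penalize). All remaining genes are null.
#'
#' @param responsive_gene_ids character vector of gene ids induced in GTX
#'   conditions.
#' @param fold_change numeric length-2 `(mean_log2, sd)`: per gene x condition
#'   log2 fold change draws for responsive genes. The default mean of 3
#'   corresponds to 8-fold induction.
#' @param ngtx_confounder_gene_ids character vector of gene ids induced in
#'   NGTX conditions; must be disjoint from `responsive_gene_ids`.
#' @param confounder_fold_change numeric length-2 `(mean_log2, sd)` for
#'   confounder genes.
#' @param baseline_log_intensity numeric length-2 `(mean, sd)` of per-gene
#'   baseline expression on the log10 intensity scale.
#' @param control_cv_percent target coefficient of variation (percent, natural
#'   scale) among control animals for each gene.
#' @param noise_sd multiplicative log-scale (natural log) noise sd applied to
#'   treatment samples.
#'
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(responsive_gene_ids = character(0),
                        fold_change = c(mean_log2 = 3, sd = 0.25),
                        ngtx_confounder_gene_ids = character(0),
                        confounder_fold_change = c(mean_log2 = 3, sd = 0.25),
                        baseline_log_intensity = c(mean = 2, sd = 0.5),
                        control_cv_percent = 30,
                        noise_sd = 0.3) {
  if (length(intersect(responsive_gene_ids, ngtx_confounder_gene_ids)) > 0L) {
    stop("responsive and confounder gene sets must be disjoint")
  }
  check2 <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x))) stop("`", nm, "` must be numeric length 2")
    if (x[[2L]] < 0) stop("`", nm, "` sd must be >= 0")
  }
  check2(fold_change, "fold_change")
  check2(confounder_fold_change, "confounder_fold_change")
  check2(baseline_log_intensity, "baseline_log_intensity")
  if (!is.finite(control_cv_percent) || control_cv_percent < 0) {
    stop("control_cv_percent must be >= 0")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(responsive_gene_ids = as.character(responsive_gene_ids),
         fold_change = unname(as.numeric(fold_change)),
         ngtx_confounder_gene_ids = as.character(ngtx_confounder_gene_ids),
         confounder_fold_change = unname(as.numeric(confounder_fold_change)),
         baseline_log_intensity = unname(as.numeric(baseline_log_intensity)),
         control_cv_percent = as.numeric(control_cv_percent),
         noise_sd = as.numeric(noise_sd)),
    class = "effect_spec"
  )
}

#' Default effect specification used by the worked examples
#'
#' Five GTX-responsive genes at a mean 8-fold induction, no NGTX confounders,
#' and control-animal variability around 30% CV.
#'
#' @param n_responsive number of spiked GTX-responsive genes (spiked ids are
#'   taken from the front of the generated gene list).
#' @return An `effect_spec`.
#' @export
default_effects <- function(n_responsive = 5L) {
  effect_spec(responsive_gene_ids = sprintf("g%05d", seq_len(n_responsive)))
}
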