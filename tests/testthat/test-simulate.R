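test_that("default design matches the ten-compound, four-timepoint study", {
  design <- study_design()
  ch <- design$chemicals
  expect_equal(sum(ch$class == "GTX" & !duplicated(ch$name)), 7)
  expect_equal(sum(ch$class == "NGTX"), 3)
  expect_equal(sum(ch$name == "DEN"), 2)
  expect_equal(ch$weight[ch$name == "DEN"], c(0.5, 0.5))
  expect_equal(design$timepoints, c("4h", "20h", "2w", "4w"))

  ds <- generate_dataset(study_design(n_genes = 20L), default_effects(2L), seed = 3)
  s <- ds$samples
  # 11 treatment cells x 4 timepoints; 8 controls x 2 solvents x 4 timepoints
  expect_equal(sum(s$role == "treatment"), 44)
  expect_equal(sum(s$role == "control"), 64)
  expect_true(all(c("DEN.1_4h", "DEN.2_4h") %in% s$sample_id))
  # every treatment sample has matched controls (same solvent, timepoint)
  for (i in which(s$role == "treatment")) {
    expect_true(any(s$role == "control" & s$solvent == s$solvent[i] &
                      s$timepoint == s$timepoint[i]))
  }
  expect_true(all(ds$intensities >= 0))
})

test_that("generation is deterministic under a fixed seed and requires one", {
  design <- small_design(n_genes = 50L)
  eff <- effect_spec(responsive_gene_ids = c("g00001", "g00002"))
  a <- generate_dataset(design, eff, seed = 7)
  b <- generate_dataset(design, eff, seed = 7)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$samples, b$samples)
  c <- generate_dataset(design, eff, seed = 8)
  expect_false(identical(a$intensities, c$intensities))
  expect_error(generate_dataset(design, eff), "seed")
})

test_that("zero effects and zero noise give exactly unit ratios", {
  eff <- effect_spec(fold_change = c(0, 0), control_cv_percent = 0, noise_sd = 0)
  ds <- generate_dataset(small_design(n_genes = 30L), eff, seed = 11)
  cm <- compute_ratios(normalize_per_chip(ds))
  expect_true(all(cm$ratio == 1))
})

test_that("effect-spec validation rejects bad inputs", {
  expect_error(effect_spec(responsive_gene_ids = "g00001",
                           ngtx_confounder_gene_ids = "g00001"), "disjoint")
  expect_error(effect_spec(noise_sd = -1), "noise_sd")
  expect_error(effect_spec(control_cv_percent = -5), "control_cv_percent")
  expect_error(study_design(n_genes = 0), "n_genes")
  expect_error(generate_dataset(small_design(10L),
                                effect_spec(responsive_gene_ids = "g09999"),
                                seed = 1),
               "not in the design")
})

test_that("control intensities realize approximately the requested CV", {
  eff <- effect_spec(control_cv_percent = 30)
  ds <- generate_dataset(small_design(n_genes = 500L, n_control_animals = 8L),
                         eff, seed = 5)
  ctl <- ds$intensities[, ds$samples$role == "control"]
  cvs <- apply(ctl, 1L, function(x) 100 * sd(x) / mean(x))
  # 64 control animals per gene, 500 genes: the median CV is tight
  expect_gt(median(cvs), 25)
  expect_lt(median(cvs), 35)
})

test_that("under the null, up-call rates are symmetric between GTX and NGTX", {
  eff <- effect_spec()  # no spiked genes: everything is null
  design <- study_design(n_genes = 120L, n_control_animals = 4L)
  up_gtx <- 0; up_ngtx <- 0; n_gtx_cells <- 0; n_ngtx_cells <- 0
  for (seed in 1:50) {
    ds <- generate_dataset(design, eff, seed = 1000 + seed)
    cm <- call_regulation(compute_ratios(normalize_per_chip(ds)))
    gtx <- cm$conditions$class == "GTX"
    up <- cm$call == "up"
    up_gtx <- up_gtx + sum(up[, gtx])
    up_ngtx <- up_ngtx + sum(up[, !gtx])
    n_gtx_cells <- n_gtx_cells + sum(gtx) * nrow(up)
    n_ngtx_cells <- n_ngtx_cells + sum(!gtx) * nrow(up)
  }
  # binomial symmetry: pool the calls, split them by the cell-count ratio
  n <- up_gtx + up_ngtx
  expect_gt(n, 100)  # the criteria do fire under the null
  p_expected <- n_gtx_cells / (n_gtx_cells + n_ngtx_cells)
  tol <- 4 * sqrt(n * p_expected * (1 - p_expected))
  expect_lt(abs(up_gtx - n * p_expected), tol)
})

test_that("increasing spike fold change never worsens median recovery rank", {
  design <- study_design(n_genes = 1000L, n_control_animals = 4L)
  spiked <- sprintf("g%05d", 1:5)
  med_rank <- sapply(c(1, 2, 3), function(lfc) {
    ranks <- sapply(1:3, function(seed) {
      eff <- effect_spec(responsive_gene_ids = spiked,
                         fold_change = c(lfc, 0.25))
      ds <- generate_dataset(design, eff, seed = 400 + seed)
      sc <- rank_genes(ds)$scores
      r <- match(spiked, sc$gene_id)
      r[is.na(r)] <- nrow(sc) + 1L  # unscored = beyond the table
      median(r)
    })
    mean(ranks)
  })
  expect_true(all(diff(med_rank) <= 0))
})

test_that("datasets round-trip through the TSV layout", {
  ds <- generate_dataset(small_design(n_genes = 12L),
                         effect_spec(responsive_gene_ids = "g00003"), seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("intensities.tsv", "samples.tsv", "truth.tsv")))))
  back <- read_dataset(dir)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-12)
  expect_equal(back$samples, ds$samples)
  expect_equal(back$truth, ds$truth)
})
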