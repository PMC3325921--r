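test_that("the weighted total applies the published weights", {
  expect_equal(total_score(c(5, 5, 5, 5, 5, 0, 2, 2)), 32.0)
  expect_equal(total_score(c(3, 5, 5, 5, 4, 0, 2, 2)), 27.0)
  expect_equal(total_score(rep(0, 8)), 0)
  expect_equal(total_score(rep(5, 8)), 37.5)  # maximum attainable
  expect_error(total_score(c(5, 5, 5)), "8 component")
  expect_error(total_score(c(5, 5, 5, 5, 5, 0, 2, NA)), "0..5")
})

test_that("named score vectors are reordered to the weight order", {
  s <- c(5, 5, 5, 5, 5, 0, 2, 2)
  names(s) <- score_parameters()
  shuffled <- s[c(8, 1, 3, 2, 5, 4, 7, 6)]
  expect_equal(total_score(shuffled), 32.0)
})

test_that("raising a component score never lowers the total", {
  set.seed(5)
  for (i in 1:25) {
    s <- sample(0:5, 8, replace = TRUE)
    base <- total_score(s)
    for (j in seq_len(8)) {
      if (s[j] < 5) {
        up <- s; up[j] <- up[j] + 1L
        expect_gt(total_score(up), base)
      }
    }
  }
})

test_that("raw-value monotonicity holds through the default bins", {
  bins <- default_bin_tables()
  spec_grid <- seq(0.5, 1, by = 0.01)
  expect_true(all(diff(bin_score(spec_grid, bins$specificity)) >= 0))
  cv_grid <- seq(150, 1, by = -1)
  expect_true(all(diff(bin_score(cv_grid, bins$cv_percent)) >= 0))
})

test_that("fixture rows re-totaled from printed scores keep their order", {
  fx <- table2_fixture()
  smat <- as.matrix(fx[, paste0(score_parameters(), "_score")])
  colnames(smat) <- score_parameters()
  totals <- total_score(smat)
  expect_equal(totals, fx$total_score)
  # descending, i.e. already in rank order
  expect_equal(order(-totals), seq_len(20))
})

test_that("deterministic tie-break orders equal totals stably", {
  fx <- table2_fixture()
  smat <- as.matrix(fx[, paste0(score_parameters(), "_score")])
  colnames(smat) <- score_parameters()
  totals <- total_score(smat)
  ord <- order(-totals, -fx$specificity, -fx$ave_ratio, fx$probe_id)
  reordered <- fx$total_score[ord]
  expect_equal(reordered, sort(fx$total_score, decreasing = TRUE))
  # re-running the same ordering is bit-stable
  expect_identical(ord, order(-totals, -fx$specificity, -fx$ave_ratio,
                              fx$probe_id))
})

test_that("a single GTX-only spiked gene ranks first", {
  eff <- effect_spec(responsive_gene_ids = "g00042")
  ds <- generate_dataset(small_design(n_genes = 300L), eff, seed = 13)
  sc <- rank_genes(ds)$scores
  expect_equal(sc$gene_id[1], "g00042")
  expect_equal(sc$rank, seq_len(nrow(sc)))
  expect_true(all(diff(sc$total_score) <= 0))
})

test_that("genes without any GTX up-call are excluded, not scored zero", {
  ratio <- matrix(c(0.2, 1, 1, 1,
                    5, 1, 1, 1), 2, byrow = TRUE,
                  dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
  ctrl <- matrix(1, 2, 4, dimnames = dimnames(ratio))
  cm <- structure(list(
    ratio = ratio, control_intensity = ctrl,
    call = matrix("none", 2, 4, dimnames = dimnames(ratio)),
    conditions = data.frame(condition = paste0("c", 1:4),
                            chemical = c("G1", "G2", "N1", "N2"),
                            class = c("GTX", "GTX", "NGTX", "NGTX"),
                            timepoint = "4h", weight = 1)),
    class = "call_matrix")
  cm <- call_regulation(cm)
  samples <- data.frame(sample_id = c(paste0("c", 1:4), "k1", "k2"),
                        chemical = c("G1", "G2", "N1", "N2", "control", "control"),
                        class = c("GTX", "GTX", "NGTX", "NGTX", "control", "control"),
                        timepoint = "4h",
                        role = c(rep("treatment", 4), "control", "control"),
                        solvent = "saline", weight = 1, replicate = 1)
  ds <- make_dataset(matrix(c(10, 20, 10, 22, 10, 21, 10, 20, 10, 19, 10, 21),
                            2, 6, dimnames = list(c("gA", "gB"), samples$sample_id)),
                     samples)
  sc <- score_genes(cm, ds)
  expect_equal(sc$gene_id, "gB")  # gA only has a down-call
})

test_that("an empty call matrix yields an empty ranking", {
  ratio <- matrix(1, 2, 4, dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
  cm <- structure(list(
    ratio = ratio, control_intensity = ratio,
    call = matrix("none", 2, 4, dimnames = dimnames(ratio)),
    conditions = data.frame(condition = paste0("c", 1:4),
                            chemical = paste0("G", 1:4),
                            class = c("GTX", "GTX", "NGTX", "NGTX"),
                            timepoint = "4h", weight = 1)),
    class = "call_matrix")
  samples <- data.frame(sample_id = c(paste0("c", 1:4), "k1", "k2"),
                        chemical = "x", class = "control", timepoint = "4h",
                        role = c(rep("treatment", 4), "control", "control"),
                        solvent = "saline", weight = 1, replicate = 1)
  ds <- make_dataset(matrix(5, 2, 6,
                            dimnames = list(c("gA", "gB"), samples$sample_id)),
                     samples)
  expect_equal(nrow(score_genes(cm, ds)), 0)
})
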