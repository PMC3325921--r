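test_that("specificity is the GTX fraction of up-calls, NA with none", {
  call <- c(rep("up", 12), rep("none", 3))
  class <- c(rep("GTX", 10), rep("NGTX", 2), rep("NGTX", 3))
  expect_equal(specificity(call, class), 10 / 12)
  expect_equal(specificity(c("up", "up"), c("GTX", "GTX")), 1)
  expect_true(is.na(specificity(c("none", "down"), c("GTX", "NGTX"))))
})

test_that("average ratio averages GTX up-cells only", {
  expect_equal(ave_ratio(c("up", "up", "up"), c(2, 4, 100),
                         c("GTX", "GTX", "NGTX")), 3)
  expect_equal(ave_ratio("up", 10.62, "GTX"), 10.62)
  expect_true(is.na(ave_ratio(c("up", "down"), c(3, 0.2), c("NGTX", "GTX"))))
})

test_that("positive condition sums cell weights; duplicated cells count half", {
  call <- rep("up", 13)
  class <- rep("GTX", 13)
  weight <- c(rep(1, 10), rep(0.5, 3))
  expect_equal(positive_condition(call, class, weight), 11.5)
  expect_equal(positive_condition(c(rep("up", 15)), rep("GTX", 15),
                                  c(rep(1, 14), 0.5)), 14.5)
  expect_equal(positive_condition("none", "GTX", 1), 0)
})

test_that("positive chemical counts distinct GTX chemicals once", {
  chems <- c("DMN", "DEN", "DEN", "ENU", "DPN", "AAT", "DBP", "DMBA")
  expect_equal(positive_chemical(rep("up", 8), rep("GTX", 8), chems), 7)
  expect_equal(positive_chemical(c("none", "up", "up", rep("none", 5)),
                                 rep("GTX", 8), chems), 1)  # both DEN cells
  expect_equal(positive_chemical(rep("none", 8), rep("GTX", 8), chems), 0)
})

test_that("reverse change is NGTX-down minus GTX-down", {
  expect_equal(reverse_change(c("down", "down", "none"),
                              c("NGTX", "NGTX", "GTX")), 2)
  expect_equal(reverse_change(c("down", "none"), c("GTX", "NGTX")), -1)
  expect_equal(reverse_change(c("up", "none"), c("GTX", "NGTX")), 0)
})

test_that("basal expression and CV match hand computations", {
  expect_equal(basal_expression(rep(10, 4)), 1)
  expect_equal(basal_expression(rep(1, 4)), 0)
  expect_equal(basal_expression(c(6, 8, 10, 9.3)), log10(8.325))
  expect_equal(basal_expression(c(10, 1000), of_means = FALSE), 2)
  expect_error(basal_expression(c(1, 0)), "positive")
  expect_equal(cv_percent(c(90, 110)), 100 * sqrt(200) / 100)
  expect_equal(cv_percent(rep(7, 5)), 0)
  expect_error(cv_percent(5), "at least 2")
})

test_that("the t-test handles degenerate and textbook cases", {
  expect_equal(group_p_value(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(group_p_value(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(group_p_value(c(2, 2), c(3, 3)), 0)
  p <- group_p_value(c(5, 6, 7, 8), c(1, 2, 2, 1))
  expect_equal(p, oracle_welch_p(c(5, 6, 7, 8), c(1, 2, 2, 1)),
               tolerance = 1e-12)
  expect_equal(p, t.test(c(5, 6, 7, 8), c(1, 2, 2, 1))$p.value,
               tolerance = 1e-12)
  expect_error(group_p_value(1, c(1, 2)), "at least 2")
})

test_that("welch and pooled flavours agree with stats::t.test on random data", {
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    expect_equal(group_p_value(a, b),
                 t.test(a, b)$p.value, tolerance = 1e-12)
    expect_equal(group_p_value(a, b, pooled = TRUE),
                 t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("row-wise parameters equal the scalar operations on random rows", {
  set.seed(123)
  for (i in 1:40) {
    row <- random_call_row()
    o <- oracle_row_parameters(row)
    expect_identical(specificity(row$call, row$class), o$specificity)
    expect_equal(ave_ratio(row$call, row$ratio, row$class), o$ave_ratio)
    expect_equal(positive_condition(row$call, row$class, row$weight),
                 o$positive_condition)
    expect_equal(positive_chemical(row$call, row$class, row$chemical),
                 o$positive_chemical)
    expect_equal(reverse_change(row$call, row$class), o$reverse_change)
  }
})

test_that("vectorized gene_parameters matches per-row scalar computation", {
  ds <- generate_dataset(small_design(n_genes = 80L),
                         effect_spec(responsive_gene_ids = sprintf("g%05d", 1:4)),
                         seed = 17)
  cm <- call_regulation(compute_ratios(normalize_per_chip(ds)))
  par <- gene_parameters(cm, ds)
  cond <- cm$conditions
  gtx <- cond$class == "GTX"
  ctl <- ds$intensities[, ds$samples$role == "control", drop = FALSE]
  for (g in sample(rownames(cm$call), 20)) {
    i <- match(g, par$gene_id)
    expect_identical(par$specificity[i], specificity(cm$call[g, ], cond$class))
    expect_equal(par$ave_ratio[i],
                 ave_ratio(cm$call[g, ], cm$ratio[g, ], cond$class))
    expect_equal(par$positive_condition[i],
                 positive_condition(cm$call[g, ], cond$class, cond$weight))
    expect_equal(par$positive_chemical[i],
                 positive_chemical(cm$call[g, ], cond$class, cond$chemical),
                 ignore_attr = TRUE)
    expect_equal(par$reverse_change[i],
                 reverse_change(cm$call[g, ], cond$class))
    expect_equal(par$p_value[i],
                 group_p_value(cm$ratio[g, gtx], cm$ratio[g, !gtx]),
                 tolerance = 1e-12)
    expect_equal(par$basal[i], basal_expression(ctl[g, ]))
    expect_equal(par$cv_percent[i], cv_percent(ctl[g, ]))
  }
})
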