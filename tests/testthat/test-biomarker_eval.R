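test_that("fit_standard_curve recovers slope/intercept and r_squared", {
  cv <- fit_standard_curve(c(1, 2, 3), c(33.2, 29.9, 26.6))
  expect_equal(cv$slope, -3.3)
  expect_equal(cv$intercept, 36.5)
  expect_equal(cv$r_squared, 1)
  expect_error(fit_standard_curve(c(2, 2), c(30, 31)), "distinct")
  expect_warning(fit_standard_curve(c(1, 2, 3), c(20, 25, 30)), "nonnegative")
})

test_that("quantify inverts the curve and censors late/undetermined Ct", {
  cv <- fit_standard_curve(c(1, 2, 3), c(33.2, 29.9, 26.6))
  expect_equal(quantify(cv$intercept, cv), 1)
  expect_equal(quantify(cv$intercept + cv$slope, cv), 10)
  expect_equal(quantify(39, cv), 0)          # beyond 38 cycles
  expect_equal(quantify(NA, cv), 0)          # undetermined
  expect_equal(quantify(c(36.5, 39, NA), cv), c(1, 0, 0))
})

test_that("relative_level and dichotomize follow the ratio-x100 and zero rules", {
  expect_equal(relative_level(5, 100), 5)
  expect_equal(relative_level(0, 50), 0)
  expect_error(relative_level(5, 0), "invalid sample")
  expect_false(dichotomize(0))
  expect_true(dichotomize(1e-6))
  expect_error(dichotomize(-0.1), "negative")
  expect_identical(dichotomize(c(0, 2, NA)), c(FALSE, TRUE, NA))
})

test_that("panel_combine is OR over calls", {
  expect_true(panel_combine(c(FALSE, FALSE, TRUE)))
  expect_false(panel_combine(c(FALSE, FALSE, FALSE)))
  expect_true(panel_combine(c(TRUE, TRUE, TRUE)))
  expect_error(panel_combine(logical(0)), "empty")
})

test_that("clopper_pearson matches closed forms and the bisection oracle", {
  # closed form at x = 0 and x = n
  ci0 <- clopper_pearson(0, 35)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - 0.025^(1 / 35))
  cin <- clopper_pearson(35, 35)
  expect_equal(cin[["upper"]], 1)
  expect_equal(cin[["lower"]], 0.025^(1 / 35))
  # bisection oracle on the binomial tail equations
  for (case in list(c(13, 59), c(1, 10), c(7, 20), c(34, 59))) {
    ci <- clopper_pearson(case[1], case[2])
    expect_equal(unname(ci), oracle_cp_bisect(case[1], case[2]),
                 tolerance = 1e-6)
  }
  expect_error(clopper_pearson(5, 4))
})

test_that("clopper_pearson has at least nominal empirical coverage", {
  # scaled-down grid (the full grid runs in the acceptance suite)
  set.seed(99)
  for (n in c(10, 59)) {
    for (p in c(0.05, 0.5, 0.95)) {
      x <- rbinom(2000, n, p)
      lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
      hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
      expect_gte(mean(lo <= p & p <= hi), 0.95)
    }
  }
})

test_that("fisher_exact_2x2 reproduces published values and the enumeration oracle", {
  expect_equal(fisher_exact_2x2(13, 46, 0, 35), 0.0016, tolerance = 1e-2)
  expect_equal(fisher_exact_2x2(5, 54, 0, 35), 0.1534, tolerance = 1e-3)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  set.seed(12)
  for (i in 1:100) {
    cells <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    mine <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
  # symmetric under swapping both rows and both columns
  expect_equal(fisher_exact_2x2(3, 9, 5, 2), fisher_exact_2x2(2, 5, 9, 3))
})

test_that("sensitivity_specificity reproduces the any-marker worked example", {
  calls <- rep(c(TRUE, FALSE, FALSE), c(13, 46, 35))
  diseased <- rep(c(TRUE, FALSE), c(59, 35))
  d <- sensitivity_specificity(calls, diseased)
  expect_equal(d$tp, 13); expect_equal(d$fn, 46)
  expect_equal(d$fp, 0); expect_equal(d$tn, 35)
  expect_equal(100 * d$sensitivity, 22.03, tolerance = 1e-3)
  expect_equal(d$specificity, 1)
  expect_equal(d$fisher_p, 0.0016, tolerance = 1e-2)
  # 0 of n diseased
  d0 <- sensitivity_specificity(rep(FALSE, 20), rep(c(TRUE, FALSE), 10))
  expect_equal(d0$sensitivity, 0)
  expect_equal(d0$se_ci[["lower"]], 0)
  # NA calls (invalid samples) are excluded from denominators
  d1 <- sensitivity_specificity(c(TRUE, NA, FALSE, FALSE),
                                c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(d1$tp + d1$fn, 2)
  expect_error(sensitivity_specificity(c(TRUE, FALSE), c(TRUE, TRUE)),
               "control")
})

test_that("panel OR-combination never decreases sensitivity nor increases specificity", {
  set.seed(44)
  for (i in 1:30) {
    n <- 40
    diseased <- rep(c(TRUE, FALSE), each = n / 2)
    calls1 <- runif(n) < 0.3 & diseased  # markers silent in controls
    calls2 <- runif(n) < 0.3
    d1 <- sensitivity_specificity(calls1, diseased)
    d12 <- sensitivity_specificity(calls1 | calls2, diseased)
    expect_gte(d12$sensitivity, d1$sensitivity)
    expect_lte(d12$specificity, d1$specificity)
  }
})

test_that("cohen_kappa and percent_agreement reproduce the concordance examples", {
  k420 <- cohen_kappa(8, 0, 11, 40)
  expect_equal(round(k420$kappa, 2), 0.50)
  expect_equal(round(unname(k420$ci), 2), c(0.26, 0.73))
  expect_equal(percent_agreement(8, 0, 11, 40), 81.36, tolerance = 1e-3)

  expect_equal(cohen_kappa(5, 0, 0, 7)$kappa, 1)  # perfect agreement
  # table constructed so that observed equals expected agreement
  k0 <- cohen_kappa(9, 21, 6, 14)
  expect_equal(k0$kappa, 0, tolerance = 1e-12)
  expect_error(cohen_kappa(0, 0, 0, 0), "empty")
  expect_error(cohen_kappa(10, 0, 0, 0), "undefined")
  expect_equal(percent_agreement(0, 3, 4, 0), 0)
  # kappa <= 1 always; = 1 iff b = c = 0 with a + d > 0
  set.seed(2)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, 30, runif(4)))
    if (sum(cells) == 0) next
    k <- tryCatch(cohen_kappa(cells[1], cells[2], cells[3], cells[4])$kappa,
                  error = function(e) NA)
    if (is.na(k)) next
    expect_lte(k, 1 + 1e-12)
    if (k >= 1 - 1e-12) expect_true(cells[2] == 0 && cells[3] == 0)
  }
})

test_that("reconstruct_paired_table solves the printed-marginal systems", {
  expect_equal(unname(reconstruct_paired_table(59, 10, 23, 67.8)),
               c(7L, 3L, 16L, 33L))
  expect_equal(unname(reconstruct_paired_table(59, 8, 19, 81.36)),
               c(8L, 0L, 11L, 40L))
  expect_equal(unname(reconstruct_paired_table(10, 5, 5, 100)),
               c(5L, 0L, 0L, 5L))
  expect_error(reconstruct_paired_table(10, 5, 5, 50), "solution")
})

test_that("paired_spearman behaves like the rank correlation on levels", {
  x <- c(0, 0, 1.5, 3, 7)
  expect_equal(paired_spearman(x, x)$rho, 1)
  expect_equal(paired_spearman(1:5, 5:1)$rho, -1)
  # tie-rich binary-like vectors against the reference midrank estimator
  a <- c(0, 0, 0, 2, 2, 5, 0, 1)
  b <- c(0, 1, 0, 3, 0, 4, 0, 2)
  ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  expect_equal(paired_spearman(a, b)$rho, unname(ref$estimate))
})

test_that("ddct_expression computes fold changes with mean reference Ct", {
  expect_equal(ddct_expression(20, 15, 24, 19), 1)      # ddCt = 0
  expect_equal(ddct_expression(25, 20, 24, 20), 0.5)    # ddCt = 1
  expect_equal(ddct_expression(25, c(20, 22), 24, c(20, 22)), 0.5)
  expect_error(ddct_expression(NA, 20, 24, 20))
})

test_that("qmsp_calls + evaluate_panel wire the QMSP pipeline together", {
  fx <- qmsp_from_patterns(table3_tissue_patterns)
  calls <- qmsp_calls(fx$qmsp)
  expect_true(all(calls$call[grepl("^C", calls$sample_id)] == FALSE))
  ev <- evaluate_panel(calls, fx$annotation, specimen = "tissue")
  expect_equal(ev$panel$specificity, 1)
  expect_equal(ev$panel$tp, 34)
  # quantities absent: interpolate through the curve instead
  fx2 <- fx$qmsp
  fx2$quantity_target <- NULL; fx2$quantity_actin <- NULL
  cv <- fit_standard_curve(c(1, 2, 3), c(33.2, 29.9, 26.6))
  calls2 <- qmsp_calls(as_qmsp_table(fx2), curve = cv)
  expect_equal(calls2$call, calls$call)
  expect_error(qmsp_calls(as_qmsp_table(fx2)), "standard curve")
})
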