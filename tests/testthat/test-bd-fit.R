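test_that("LR statistic reproduces published model comparisons", {
  # APC: single lambda (-34.31) vs single lambda+mu (-34.28)
  expect_equal(round(lrt_statistic(-34.31, -34.28), 2), 0.06)
  # AAAP: structured lambda (-35.01) vs structured lambda+mu (-28.76);
  # printed as 12.51 from unrounded likelihoods
  expect_equal(lrt_statistic(-35.01, -28.76), 12.50, tolerance = 0.02)
  expect_equal(lrt_statistic(-10, -10), 0)
  expect_equal(lrt_statistic(-10, -10 - 1e-8), 0) # optimiser noise clamped
  expect_warning(lrt_statistic(-10, -11), "negative")
})

test_that("chi-square p-values match an independent numeric integration", {
  expect_equal(round(chisq_pvalue(12.51, 2), 3), 0.002)
  expect_equal(chisq_pvalue(0, 1), 1)
  dens1 <- function(x) exp(-x / 2) / sqrt(2 * pi * x)
  expect_equal(chisq_pvalue(3.84, 1),
               integrate(dens1, 3.84, Inf)$value, tolerance = 1e-5)
  expect_equal(round(chisq_pvalue(3.84, 1), 3), 0.05)
  expect_error(chisq_pvalue(-1, 1), "non-negative")
})

test_that("fold change reproduces the published rate ratios", {
  expect_equal(round(fold_change(2.5049e-3, 0.7307e-3), 2), 3.43)
  expect_equal(round(fold_change(3.6802e-3, 0.3286e-3), 2), 11.20)
  expect_equal(fold_change(2, 2), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("AIC follows its definition and ranks nested fits sensibly", {
  expect_equal(aic_score(0, 0), 0)
  expect_equal(aic_score(-34.31, 1), 70.62)
  # a one-unit lnL gain is not worth two extra parameters
  expect_lt(aic_score(-34, 1), aic_score(-33, 3))
})

test_that("constant single-copy families drive lambda to the lower bound", {
  tr <- hemiptera_chronogram()
  counts <- as_count_table(as.data.frame(
    matrix(1L, 3, 13, dimnames = list(NULL, tr$tip.label))))
  f <- fit_bd(counts, tr, "single_lambda", root_policy = "fixed",
              root_count = 1)
  expect_lt(f$params$lambda, 1e-7)
})

test_that("tied rates are recovered from simulated data", {
  tr <- hemiptera_chronogram()
  sim <- simulate_count_matrix(tr, 200, lambda = 2e-3, seed = 401,
                               root_prior = 10L)
  f <- fit_bd(sim$counts, tr, "single_lambda", root_policy = "fixed",
              root_count = 10)
  expect_lt(abs(f$params$lambda - 2e-3) / 2e-3, 0.2)
  expect_true(f$converged)
  expect_equal(f$lnL, sum(f$logliks))
})

test_that("richer models never fit worse than their nested null", {
  tr <- hemiptera_chronogram()
  br <- mrca_branches(tr, sternorrhyncha_taxa(), include_stem = TRUE)
  counts <- transporter_counts()
  f1 <- fit_bd(counts[counts$family == "APC", ], tr, "single_lambda")
  f2 <- fit_bd(counts[counts$family == "APC", ], tr, "multi_lambda",
               branches = br)
  f3 <- fit_bd(counts[counts$family == "APC", ], tr, "single_lambda_mu")
  expect_gte(f2$lnL, f1$lnL - 1e-6)
  expect_gte(f3$lnL, f1$lnL - 1e-6)
  lt <- lr_test(f1, f2)
  expect_equal(lt$df, 1)
  expect_gte(lt$lr, 0)
  expect_equal(lt$p_chisq, chisq_pvalue(lt$lr, 1))
  expect_error(lr_test(f2, f1), "more parameters")
})

test_that("tidy and glance summarise fits in broom layout", {
  tr <- hemiptera_chronogram()
  counts <- transporter_counts()
  f <- fit_bd(counts[counts$family == "APC", ], tr, "single_lambda")
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 1)
  gl <- glance(f)
  expect_equal(gl$n_params, 1)
  expect_equal(gl$AIC, aic_score(f$lnL, 1))
})

test_that("empirical-null LRT p-value follows the plus-one estimator", {
  tr <- hemiptera_chronogram()
  sim <- simulate_count_matrix(tr, 40, lambda = 1.5e-3, seed = 77,
                               root_prior = 10L)
  f0 <- fit_bd(sim$counts, tr, "single_lambda", root_policy = "fixed",
               root_count = 10)
  f1 <- fit_bd(sim$counts, tr, "single_lambda_mu", root_policy = "fixed",
               root_count = 10, n_starts = 1)
  res <- simulated_null_lrt(f0, f1, reps = 100, seed = 5, n_starts = 1)
  expect_equal(res$p_simulated,
               (1 + sum(res$lr_null >= res$lr)) / (res$n_null_reps + 1))
  expect_gt(res$p_simulated, 0)
  expect_error(simulated_null_lrt(f0, f1, reps = 50), "at least 100")
})
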