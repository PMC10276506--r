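test_that("SE recovery from a Wald CI inverts the construction", {
  # published headline CI
  expect_equal(se_from_ci(3.27, 7.40),
               (log(7.40) - log(3.27)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(round(se_from_ci(3.27, 7.40), 5), 0.20834)

  # any interval built as (k, k * exp(2 z * 0.5)) returns exactly 0.5
  z <- qnorm(0.975)
  for (k in c(0.2, 1, 7.3)) {
    expect_equal(se_from_ci(k, k * exp(2 * z * 0.5)), 0.5, tolerance = 1e-12)
  }

  expect_error(se_from_ci(2, 2), "zero-width")
  expect_error(se_from_ci(-1, 2), "positive")
})

test_that("OR_select supports full, simplified, and benchmark forms", {
  # benchmark construction for the headline exposure
  expect_equal(round(or_select(rate_sample = 8.00, rate_benchmark = 4.67), 3),
               1.713)
  # non-differential selection
  expect_equal(or_select(s_control_1 = 0.3, s_control_0 = 0.3), 1.0)
  # full four-proportion form
  expect_equal(or_select(s_control_1 = 1, s_control_0 = 1,
                         s_case_1 = 0.5, s_case_0 = 1), 2.0)
  expect_error(or_select(rate_sample = 8, rate_benchmark = 0), "positive")
  expect_error(or_select(s_control_1 = 1.2, s_control_0 = 1), "0, 1")
})

test_that("triangular sampler matches closed-form moments and CDF", {
  a <- 1.368; cc <- 1.71; b <- 2.052
  x <- rtriangular(1e6, a, cc, b, seed = 3)
  expect_true(all(x >= a & x <= b))
  expect_equal(mean(x), (a + b + cc) / 3, tolerance = 1e-3)
  v_expected <- (a^2 + b^2 + cc^2 - a * b - a * cc - b * cc) / 18
  expect_equal(var(x), v_expected, tolerance = 0.01)
  expect_equal(round(v_expected, 5), 0.01949)

  # closed-form CDF at interior points
  tri_cdf <- function(q) {
    ifelse(q < cc, (q - a)^2 / ((b - a) * (cc - a)),
           1 - (b - q)^2 / ((b - a) * (b - cc)))
  }
  for (q in c(1.45, 1.71, 1.9)) {
    expect_equal(mean(x <= q), tri_cdf(q), tolerance = 3e-3)
  }

  # degenerate point mass and argument validation
  expect_equal(rtriangular(5, 1.71, 1.71, 1.71), rep(1.71, 5))
  expect_error(rtriangular(5, 2, 1.5, 1), "exceeds")
  expect_error(rtriangular(5, 1, 3, 2), "within")
})

test_that("bias simulation collapses correctly in the no-error limit", {
  r <- qba_simulate(or_observed = 4.92, se_ln_or = 0, or_select_mode = 1,
                    rel_lower = 0, rel_upper = 0, n_iter = 1000, seed = 1)
  expect_equal(r$median, 4.92)
  expect_equal(r$si_low, 4.92)
  expect_equal(r$si_high, 4.92)
  expect_equal(r$or_adjusted_point, 4.92)
})

test_that("bias simulation is reproducible and refuses unstable n_iter", {
  r1 <- qba_simulate(2, 1.5, 2.7, or_select_mode = 1.3, seed = 9,
                     n_iter = 2000, keep_draws = TRUE)
  r2 <- qba_simulate(2, 1.5, 2.7, or_select_mode = 1.3, seed = 9,
                     n_iter = 2000, keep_draws = TRUE)
  expect_identical(r1$draws, r2$draws)
  r3 <- qba_simulate(2, 1.5, 2.7, or_select_mode = 1.3, seed = 10,
                     n_iter = 2000, keep_draws = TRUE)
  expect_false(identical(r1$draws, r3$draws))
  expect_error(qba_simulate(2, 1.5, 2.7, or_select_mode = 1.3, n_iter = 500),
               "1000")
})

test_that("median is monotone in or_select_mode and or_observed", {
  meds_mode <- sapply(c(0.5, 0.8, 1, 1.3, 1.7), function(m) {
    qba_simulate(2, 1.5, 2.7, or_select_mode = m, n_iter = 5000, seed = 4)$median
  })
  expect_true(all(diff(meds_mode) > 0))
  meds_or <- sapply(c(0.7, 1.2, 2.5, 4.9), function(o) {
    qba_simulate(o, se_ln_or = 0.2, or_select_mode = 1.3, n_iter = 5000,
                 seed = 4)$median
  })
  expect_true(all(diff(meds_or) > 0))
})

test_that("scaling the observed OR scales median and interval exactly", {
  base <- qba_simulate(2, se_ln_or = 0.21, or_select_mode = 1.3,
                       n_iter = 5000, seed = 6)
  scaled <- qba_simulate(2 * 3.5, se_ln_or = 0.21, or_select_mode = 1.3,
                         n_iter = 5000, seed = 6)
  expect_equal(scaled$median, 3.5 * base$median, tolerance = 1e-12)
  expect_equal(scaled$si_low, 3.5 * base$si_low, tolerance = 1e-12)
  expect_equal(scaled$si_high, 3.5 * base$si_high, tolerance = 1e-12)
})

test_that("median converges to or_observed x mode for symmetric triangular", {
  r <- qba_simulate(4.92, 3.27, 7.40, or_select_mode = 1.71, n_iter = 5e5,
                    seed = 12)
  expect_equal(r$median, 4.92 * 1.71, tolerance = 0.005)

  # with mode 1 the median stays at the observed OR and the SI is wider
  # than the original CI (the triangular prior adds spread)
  r1 <- qba_simulate(4.92, 3.27, 7.40, or_select_mode = 1, n_iter = 2e5,
                     seed = 13)
  expect_equal(r1$median, 4.92, tolerance = 0.02 * 4.92)
  expect_lt(r1$si_low, 3.27)
  expect_gt(r1$si_high, 7.40)
})

test_that("batch runs are label-seeded, order-independent, and validated", {
  inputs <- data.frame(
    exposure = c("mental illness", "assault"),
    or_observed = c(1.97, 0.54),
    ci_low = c(1.60, 0.32),
    ci_high = c(2.43, 0.92),
    or_select_mode = c(1.3, 0.8),
    stringsAsFactors = FALSE
  )
  b <- qba_batch(inputs, n_iter = 5000, seed = 17)
  b_shuffled <- qba_batch(inputs[2:1, ], n_iter = 5000, seed = 17)
  for (e in inputs$exposure) {
    expect_equal(b$or_adjusted_median[b$exposure == e],
                 b_shuffled$or_adjusted_median[b_shuffled$exposure == e])
  }

  # a batch of one reduces to qba_simulate under the derived seed
  single <- qba_simulate(1.97, 1.60, 2.43, or_select_mode = 1.3,
                         n_iter = 5000, seed = derive_seed(17, "mental illness"))
  expect_equal(b$or_adjusted_median[1], single$median)
  expect_equal(b$si_low[1], single$si_low)

  # under-representation adjusts downward
  expect_lt(b$or_adjusted_median[b$exposure == "assault"], 0.54)

  expect_error(qba_batch(rbind(inputs, inputs[1, ])), "duplicate")
  expect_error(qba_batch(inputs[, -2]), "lacks columns")
})

test_that("seed derivation is deterministic, label-sensitive, and in range", {
  expect_identical(derive_seed(17, "pain"), derive_seed(17, "pain"))
  expect_false(derive_seed(17, "pain") == derive_seed(17, "assault"))
  expect_false(derive_seed(17, "pain") == derive_seed(18, "pain"))
  s <- sapply(c("a", "zz", "mental illness"), derive_seed, master_seed = 2^30)
  expect_true(all(s >= 0 & s < 2147483647))
})

test_that("forest plot builds from a batch result", {
  inputs <- data.frame(exposure = "pain", or_observed = 1.34, ci_low = 1.07,
                       ci_high = 1.69, or_select_mode = 1.3)
  p <- plot_qba(qba_batch(inputs, n_iter = 2000, seed = 3))
  expect_s3_class(p, "ggplot")
})
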