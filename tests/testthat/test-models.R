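test_that("logistic MLE on a saturated 2x2 equals the cross-product ratio", {
  d <- expand_2x2(a = 291, b = 27, c = 3571, d = 1526)
  x <- cbind(`(Intercept)` = 1, exposure = d$x)
  fit <- fit_logistic(x, d$y)
  or_mle <- exp(fit$coefficients[["exposure"]])
  or_crossprod <- (291 * 1526) / (27 * 3571)
  expect_lt(abs(or_mle - or_crossprod), 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separated)
})

test_that("degenerate designs and outcomes are rejected with clear errors", {
  x <- cbind(`(Intercept)` = 1, exposure = c(0, 0, 0, 0))
  expect_error(fit_logistic(x, c(0, 1, 0, 1)), "constant-zero")
  x2 <- cbind(`(Intercept)` = 1, a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))
  expect_error(fit_logistic(x2, c(0, 1, 0, 1)), "collinear.*b")
  x3 <- cbind(`(Intercept)` = 1, exposure = c(0, 1, 0, 1))
  expect_error(fit_logistic(x3, c(1, 1, 1, 1)), "single class")
})

test_that("sandwich covariance matches a brute-force score computation", {
  fx <- make_glm_fixture(30)
  fit <- fit_logistic(fx$x, fx$y)

  # independent oracle: explicit per-observation loop
  n <- nrow(fx$x); k <- ncol(fx$x)
  mu <- plogis(drop(fx$x %*% fit$coefficients))
  B <- matrix(0, k, k); M <- matrix(0, k, k)
  for (i in seq_len(n)) {
    xi <- fx$x[i, ]
    B <- B + mu[i] * (1 - mu[i]) * tcrossprod(xi)
    si <- xi * (fx$y[i] - mu[i])
    M <- M + tcrossprod(si)
  }
  V_oracle <- solve(B) %*% M %*% solve(B) * n / (n - k)

  V <- robust_covariance(fit, type = "HC1")
  expect_lt(max(abs(V - V_oracle)), 1e-6)

  # independent library cross-check
  df <- data.frame(y = fx$y, exposure = fx$x[, "exposure"], age = fx$x[, "age"])
  gm <- glm(y ~ exposure + age, family = binomial(), data = df)
  V_sandwich <- sandwich::vcovHC(gm, type = "HC1")
  expect_lt(max(abs(V - V_sandwich)), 1e-6)
})

test_that("saturated 2x2 robust SE reduces to the Woolf formula", {
  a <- 40; b <- 25; cc <- 160; dd <- 175
  d <- expand_2x2(a, b, cc, dd)
  x <- cbind(`(Intercept)` = 1, exposure = d$x)
  fit <- fit_logistic(x, d$y)
  woolf <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  n <- length(d$y)

  se_hc0 <- sqrt(diag(robust_covariance(fit, type = "HC0")))[["exposure"]]
  expect_lt(abs(se_hc0 - woolf), 1e-8)
  se_hc1 <- sqrt(diag(robust_covariance(fit, type = "HC1")))[["exposure"]]
  expect_lt(abs(se_hc1 - woolf * sqrt(n / (n - 2))), 1e-8)
})

test_that("duplicating every observation halves the HC0 variance", {
  fx <- make_glm_fixture(30)
  fit1 <- fit_logistic(fx$x, fx$y)
  v1 <- robust_covariance(fit1, type = "HC0")
  fit2 <- fit_logistic(rbind(fx$x, fx$x), c(fx$y, fx$y))
  v2 <- robust_covariance(fit2, type = "HC0")
  expect_equal(v2, v1 / 2, tolerance = 1e-8)
})

test_that("Wald CI invariant holds and fits are row-order invariant", {
  cfg <- simulation_config(
    n_cases = 2000, n_controls_target = 1000,
    exposure_specs = list(exposure_spec("depression", 0.15, 2.0)),
    seed = 55)
  g <- generate_cohort(cfg, make_visits = FALSE)
  persons <- g$persons
  elig <- apply_eligibility(persons)
  res <- run_hierarchy(elig$persons, g$exposure_truth, variant = "separate",
                       terms = "depression")
  expect_true(res$estimable)
  expect_lt(abs(res$ci_low - exp(log(res$or) - 1.959964 * res$se_ln_or)), 1e-9)
  expect_lt(abs(res$ci_high - exp(log(res$or) + 1.959964 * res$se_ln_or)), 1e-9)
  expect_true(res$ci_low < res$or & res$or < res$ci_high)

  set.seed(1)
  perm <- sample(nrow(elig$persons))
  res_perm <- run_hierarchy(elig$persons[perm, ], g$exposure_truth,
                            variant = "separate", terms = "depression")
  expect_equal(res_perm$or, res$or, tolerance = 1e-9)
})

test_that("adjusted models recover a true odds ratio of 2 on synthetic data", {
  cfg <- simulation_config(
    n_cases = 14000, n_controls_target = 6000, pool_multiplier = 1,
    exposure_specs = list(exposure_spec("depression", 0.10, 2.0)),
    seed = 77)
  g <- generate_cohort(cfg, make_visits = FALSE)
  elig <- apply_eligibility(g$persons)
  res <- run_hierarchy(elig$persons, g$exposure_truth, variant = "separate",
                       terms = "depression")
  expect_true(res$ci_low < 2.0 && 2.0 < res$ci_high)

  # simultaneous with a single exposure coincides with separate
  res_sim <- run_hierarchy(elig$persons, g$exposure_truth,
                           variant = "simultaneous", terms = "depression")
  expect_equal(res_sim$or, res$or, tolerance = 1e-12)
  expect_equal(res_sim$se_ln_or, res$se_ln_or, tolerance = 1e-12)
})

test_that("separate and simultaneous agree for independent exposures", {
  cfg <- simulation_config(
    n_cases = 10000, n_controls_target = 5000, pool_multiplier = 1,
    exposure_specs = list(exposure_spec("depression", 0.12, 2.0),
                          exposure_spec("asthma", 0.10, 1.0)),
    seed = 88)
  g <- generate_cohort(cfg, make_visits = FALSE)
  elig <- apply_eligibility(g$persons)
  sep <- run_hierarchy(elig$persons, g$exposure_truth, variant = "separate",
                       terms = c("depression", "asthma"))
  sim <- run_hierarchy(elig$persons, g$exposure_truth,
                       variant = "simultaneous",
                       terms = c("depression", "asthma"))
  for (tm in c("depression", "asthma")) {
    b_sep <- log(sep$or[sep$term == tm])
    b_sim <- log(sim$or[sim$term == tm])
    se <- sep$se_ln_or[sep$term == tm]
    expect_lt(abs(b_sep - b_sim), 3 * se)
  }
})

test_that("separated terms are flagged non-estimable and the run continues", {
  p <- make_persons(40, status = rep(c("case", "control"), each = 20))
  # perfect separation: exposure identical to outcome
  em <- data.frame(person_id = p$person_id,
                   perfect = as.integer(p$status == "case"),
                   fine = rep(c(0L, 1L), 20))
  # glm.fit emits its fitted-probabilities-0/1 warning on the separated term
  res <- suppressWarnings(run_hierarchy(p, em, variant = "separate",
                                        terms = c("perfect", "fine"),
                                        adjust = FALSE))
  expect_false(res$estimable[res$term == "perfect"])
  expect_true(res$estimable[res$term == "fine"])
})
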