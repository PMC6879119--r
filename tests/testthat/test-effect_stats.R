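# Modified Poisson regression, CI back-calculation, and REML pooling.

test_that("modified Poisson recovers the 2x2 closed form exactly", {
  d <- data.frame(
    y = rep(c(1, 0, 1, 0), c(20, 180, 10, 190)),
    x = rep(c(1, 0), c(200, 200))
  )
  est <- fit_modified_poisson(d, "y", "x")
  expect_equal(est$rr, 2, tolerance = 1e-9)
  expect_equal(est$se, sqrt(1 / 20 - 1 / 200 + 1 / 10 - 1 / 200),
               tolerance = 1e-9)
  expect_equal(est$ci_lower, exp(est$log_rr - qnorm(0.975) * est$se))

  # identical outcome proportions in both exposure levels: RR = 1
  d1 <- data.frame(y = rep(c(1, 0, 1, 0), c(15, 135, 15, 135)),
                   x = rep(c(1, 0), c(150, 150)))
  expect_equal(fit_modified_poisson(d1, "y", "x")$rr, 1, tolerance = 1e-6)
})

test_that("modified Poisson rejects degenerate inputs", {
  d <- data.frame(y = rep(0, 50), x = rbinom(50, 1, 0.5))
  expect_error(fit_modified_poisson(d, "y", "x"), "no outcome events")
  d2 <- data.frame(y = rbinom(50, 1, 0.2), x = 1:50, x2 = 2 * (1:50))
  expect_error(fit_modified_poisson(d2, "y", c("x", "x2")), "rank")
  d3 <- data.frame(y = c(2, 0, 1), x = c(1, 0, 1))
  expect_error(fit_modified_poisson(d3, "y", "x"), "binary")
})

test_that("sandwich variance corrects the naive Poisson variance for binary outcomes", {
  # for a Bernoulli outcome var(y) = mu(1-mu) < mu, so the robust variance
  # must come in at or below the model-based Poisson variance
  set.seed(31)
  n <- 2e4
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.05 * ifelse(x == 1, 2, 1))
  d <- data.frame(y = y, x = x)
  est <- fit_modified_poisson(d, "y", "x")
  naive <- summary(glm(y ~ x, poisson, data = d))$coefficients["x", "Std. Error"]
  expect_lte(est$se, naive)
  expect_gt(est$se, 0.5 * naive)
})

test_that("se_from_ci back-calculates published standard errors", {
  expect_equal(se_from_ci(5.70, 3.60, 9.02), 0.234, tolerance = 2e-3)
  expect_equal(se_from_ci(0.26, 0.04, 1.79), 0.969, tolerance = 1e-3)
  expect_error(se_from_ci(2, 3, 4), "lower")
  expect_warning(se <- se_from_ci(2, 2, 2), "degenerate")
  expect_identical(se, 0)
})

test_that("REML pooling reproduces the published pooled relative risks", {
  hist <- pool_primer_estimates("history_prior")
  expect_equal(hist$rr, 4.93, tolerance = 0.01)
  expect_equal(hist$ci_lower, 3.41, tolerance = 0.01)
  expect_equal(hist$ci_upper, 7.14, tolerance = 0.01)
  oat <- pool_primer_estimates("oat_recent")
  expect_equal(oat$rr, 0.55, tolerance = 0.02)
  expect_equal(oat$ci_lower, 0.36, tolerance = 0.02)
  expect_equal(oat$ci_upper, 0.84, tolerance = 0.02)
  expect_equal(sum(hist$studies$weight), 1)
  # the tightest interval (Vancouver) carries the largest weight
  expect_equal(hist$studies$study[which.max(hist$studies$weight)], "Vancouver")
})

test_that("pooling limits: identical studies and the convex hull", {
  p <- pool_random_effects(rep(log(2), 4), rep(0.3, 4))
  expect_equal(p$rr, 2, tolerance = 1e-9)
  expect_equal(p$tau2, 0)
  expect_equal(p$se, 0.3 / sqrt(4), tolerance = 1e-6)

  set.seed(9)
  for (i in 1:10) {
    y <- rnorm(4)
    v <- runif(4, 0.05, 0.4)
    pp <- pool_random_effects(y, v)
    expect_gte(pp$log_rr, min(y) - 1e-12)
    expect_lte(pp$log_rr, max(y) + 1e-12)
    expect_gte(pp$tau2, 0)
    expect_equal(sum(pp$studies$weight), 1)
  }

  expect_message(single <- pool_random_effects(log(2), 0.2), "single")
  expect_equal(single$rr, 2)
  expect_error(pool_random_effects(c(0, 1), c(0.1, 0)), "> 0")
})

test_that("regression recovers the true RRs from a synthetic cohort", {
  spec <- default_primer_spec()$Vancouver
  d <- generate_cohort(spec, seed = 2024, n = 2e5)
  terms <- default_site_terms("Vancouver")
  est <- fit_modified_poisson(d, "recent_assist", terms$exposures,
                              terms$covariates)
  oat <- est[est$term == "oat_recent", ]
  hist <- est[est$term == "history_prior", ]
  expect_lt(abs(oat$rr - 0.55), 0.03)
  expect_lt(abs(hist$rr - 4.93), 3 * hist$se * 4.93)
})
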