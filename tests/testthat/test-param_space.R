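# Sampling distributions and the Monte Carlo parameter space.

test_that("dist_spec validates family parameters", {
  expect_s3_class(dist_spec("beta", shape1 = 2, shape2 = 3), "dist_spec")
  expect_error(dist_spec("beta", shape1 = -1, shape2 = 3), "shapes")
  expect_error(dist_spec("triangular", min = 5, mode = 3, max = 25), "min <= mode")
  expect_error(dist_spec("lognormal", median = 1, sdlog = 0), "sdlog")
  expect_error(dist_spec("normal", mean = 0), "arg")
})

test_that("sample_distribution reproduces stated moments", {
  set.seed(101)
  # beta(9.94, 36.76): mean 0.21 within 3 Monte Carlo SEs
  x <- sample_distribution(dist_spec("beta", shape1 = 9.94, shape2 = 36.76), 1e5)
  mu <- 9.94 / (9.94 + 36.76)
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(1e5))

  # degenerate reciprocal: always 1/69.3
  f <- sample_distribution(
    dist_spec("fixed", value = 69.3, transform = "reciprocal"), 10)
  expect_identical(f, rep(1 / 69.3, 10))

  # scaled Poisson(62)/1e4: mean 0.0062, 2.5/97.5 percentiles 0.0047/0.0078
  y <- sample_distribution(
    dist_spec("scaled_poisson", lambda = 62, divisor = 1e4), 1e5)
  expect_lt(abs(mean(y) - 0.0062), 3 * sd(y) / sqrt(1e5))
  expect_equal(unname(quantile(y, c(0.025, 0.975))),
               c(qpois(0.025, 62), qpois(0.975, 62)) / 1e4,
               tolerance = 0.05)

  # reciprocal of U(0.25, 1.25): 1/E[rate] = 1/log(5) ~ 0.621
  z <- sample_distribution(
    dist_spec("uniform", min = 0.25, max = 1.25, transform = "reciprocal"), 1e5)
  expect_equal(1 / mean(z), 1 / log(5), tolerance = 0.01)
})

test_that("parameter sets are seeded, reproducible, and within supports", {
  a <- sample_parameter_sets(5, seed = 99)
  b <- sample_parameter_sets(5, seed = 99)
  expect_identical(a, b)
  expect_error(sample_parameter_sets(0, seed = 1), ">= 1")

  p <- sample_parameter_sets(2000, seed = 7)
  expect_true(all(1 / p$xi >= 5 & 1 / p$xi <= 25))
  expect_true(all(1 / p$rho >= 0.25 & 1 / p$rho <= 1.25))
  expect_true(all(p$m_inv >= 1))
  expect_identical(p$xi_oat, p$xi)
  tg <- as.matrix(p[grep("^target_", names(p))])
  expect_true(all(tg > 0 & tg < 1))
})

test_that("sampled means and intervals match the quoted distribution summaries", {
  p <- memo("p10k", sample_parameter_sets(10000, seed = 31))
  s <- summarize_samples(p)
  rownames(s) <- s$parameter
  quoted <- list( # parameter = c(mean, lo, hi) on the reporting scale
    mu_OV = c(0.0062, 0.0047, 0.0078),
    theta = c(0.025, 0.017, 0.034),
    xi = c(13.70, 7.14, 22.64),
    rho = c(0.62, 0.27, 1.22),
    m_inv = c(1.85, 1.01, 4.36),
    RR_I = c(5.03, 3.41, 7.12),
    RR_OAT = c(0.56, 0.36, 0.83),
    RR_OATout = c(2.43, 1.51, 3.72),
    RR_OATin = c(2.10, 0.93, 4.08),
    RR_OATov = c(0.21, 0.12, 0.35),
    target_prev_nonIDU = c(0.090, 0.085, 0.095),
    target_prev_PWID = c(0.011, 0.0061, 0.018),
    target_prop_unassisted = c(0.17, 0.11, 0.24),
    target_oat_coverage = c(0.21, 0.11, 0.34)
  )
  for (nm in names(quoted)) {
    q <- quoted[[nm]]
    expect_equal(s[nm, "mean"], q[1], tolerance = 0.05,
                 label = paste(nm, "mean"))
    expect_equal(s[nm, "q2.5"], q[2], tolerance = 0.10,
                 label = paste(nm, "lower"))
    expect_equal(s[nm, "q97.5"], q[3], tolerance = 0.10,
                 label = paste(nm, "upper"))
  }
})

test_that("lognormal quoted value is the median, so the mean exceeds it", {
  p <- memo("p10k", sample_parameter_sets(10000, seed = 31))
  # mean/median = exp(sdlog^2/2) for a lognormal
  expect_equal(mean(p$RR_I) / 4.93, exp(0.19^2 / 2), tolerance = 0.01)
  expect_equal(mean(p$RR_OATout) / 2.38, exp(0.23^2 / 2), tolerance = 0.01)
})

test_that("summarize_samples handles degenerate and empty input", {
  p <- sample_parameter_sets(1, seed = 3)
  s <- summarize_samples(p)
  expect_equal(s[s$parameter == "RR_I", "q2.5"],
               s[s$parameter == "RR_I", "q97.5"])
  expect_error(summarize_samples(p[0, ]), "non-empty")
})

test_that("distribution overrides replace defaults by name", {
  p <- sample_parameter_sets(
    50, seed = 2,
    distributions = list(RR_OAT = dist_spec("fixed", value = 1)))
  expect_true(all(p$RR_OAT == 1))
  expect_error(
    sample_parameter_sets(5, seed = 2, distributions = list(bogus = dist_spec("fixed", value = 1))),
    "unknown parameter")
})
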