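# Compartment dynamics: OAT-transition death fractions, the initiation
# force, the ODE right-hand side, integration, and steady states.

test_that("excess overdose fractions follow the 4-week formulas", {
  p <- list(mu_OV = 0.0062, RR_OATout = 2.43, RR_OATin = 2.10, RR_OATov = 0.21)
  d <- excess_overdose_fractions(p)
  expect_equal(d$delta_exit, 0.0062 * (2.43 - 1) * 4 / 52, tolerance = 1e-12)
  expect_equal(d$delta_exit, 6.82e-4, tolerance = 1e-3)
  expect_equal(d$delta_enter, 0.0062 * 0.21 * (2.10 - 1) * 4 / 52,
               tolerance = 1e-12)
  expect_equal(d$delta_enter, 1.10e-4, tolerance = 2e-3)
  # no excess risk at RR = 1; protective draws clipped at zero
  p$RR_OATout <- 1
  expect_identical(excess_overdose_fractions(p)$delta_exit, 0)
  p$RR_OATout <- 0.5
  expect_identical(excess_overdose_fractions(p)$delta_exit, 0)
})

test_that("initiation force is the RR-weighted PWID prevalence times V", {
  p <- mean_params()
  mk <- function(...) rate_set(p, ...)
  s <- c(G = 902000, V = 90000, A = 4000, B = 2000, C = 1500, D = 500, E = 0)

  # hand-computed example
  p2 <- p; p2$RR_I <- 5; p2$RR_OAT <- 0.5
  r <- rate_set(p2, beta = 0.05, gamma = 0.1, tau = 100, alpha = 0.4)
  fl <- initiation_flux(s, r)
  expect_equal(fl$assisted, 0.05 * (4000 + 10000 + 750 + 1250) / 1e6 * 90000,
               tolerance = 1e-12)
  expect_equal(fl$assisted, 72)

  # no PWID: assisted zero, unassisted tau
  s0 <- c(G = 910000, V = 90000, A = 0, B = 0, C = 0, D = 0, E = 0)
  fl0 <- initiation_flux(s0, r)
  expect_identical(fl0$assisted, 0)
  expect_equal(fl0$unassisted, 100)

  # RR_I = RR_OAT = 1 collapses to unweighted prevalence
  p3 <- p; p3$RR_I <- 1; p3$RR_OAT <- 1
  r3 <- rate_set(p3, beta = 0.05, gamma = 0.1, tau = 0, alpha = 0.4)
  expect_equal(initiation_flux(s, r3)$assisted,
               0.05 * 8000 / 1e6 * 90000, tolerance = 1e-12)
})

test_that("monotone force: adding PWID never decreases the assisted rate", {
  p <- mean_params()
  r <- rate_set(p, beta = 0.4, gamma = 0.2, tau = 150, alpha = 0.4)
  set.seed(5)
  for (i in 1:20) {
    s <- c(G = 9e5, V = 9e4, A = runif(1, 0, 5e3), B = runif(1, 0, 5e3),
           C = runif(1, 0, 5e3), D = runif(1, 0, 5e3), E = 5e4)
    base <- initiation_flux(s, r)$assisted
    for (comp in c("A", "B", "C", "D")) {
      s2 <- s
      s2[comp] <- s2[comp] + 1000
      expect_gte(initiation_flux(s2, r)$assisted, base)
    }
    # linearity in V
    s3 <- s; s3["V"] <- 2 * s["V"]
    N <- sum(s); N3 <- sum(s3)
    expect_equal(initiation_flux(s3, r)$assisted * N3 / s3[["V"]],
                 base * N / s[["V"]], tolerance = 1e-10)
  }
})

test_that("history transition flux is m * beta-force on the unweighted compartment", {
  p <- mean_params()
  p$m_inv <- 2; p$RR_I <- 5; p$RR_OAT <- 0.5
  r <- rate_set(p, beta = 0.05, gamma = 0.1, tau = 100, alpha = 0.4)
  s <- c(G = 902000, V = 90000, A = 4000, B = 2000, C = 1500, D = 500, E = 0)
  d <- idu_derivatives(s, r)
  expect_equal(unname(d$fluxes["hist_AB"]), 0.5 * 0.05 * 4000 / 1e6 * 90000)
  expect_equal(unname(d$fluxes["hist_AB"]), 9)
})

test_that("R and compiled right-hand sides agree", {
  cals <- fixture_small_cals()
  for (cl in cals[1:5]) {
    set.seed(17)
    s <- cl$state * runif(7, 0.5, 1.5) # off-equilibrium states too
    d <- idu_derivatives(s, cl$rates)
    cc <- idudyn:::.idu_rhs_cpp(unname(s), idudyn:::rate_vector(cl$rates))
    expect_equal(unname(c(d$dstate, d$fluxes)), unname(cc), tolerance = 1e-12)
  }
})

test_that("population leaks only through overdose and OAT-transition deaths", {
  # symbolic conservation identity, checked numerically at random states
  cals <- fixture_small_cals()
  set.seed(23)
  for (cl in cals[1:10]) {
    s <- cl$state * runif(7, 0.2, 2)
    d <- idu_derivatives(s, cl$rates)
    expect_equal(sum(d$dstate),
                 -unname(d$fluxes["deaths_overdose"] +
                           d$fluxes["deaths_oat_transition"]),
                 tolerance = 1e-9)
  }
})

test_that("literal dB/dt reading is available but breaks conservation", {
  p <- mean_params()
  r <- rate_set(p, beta = 0.4, gamma = 0.2, tau = 150, alpha = 0.4,
                literal_dB = TRUE)
  s <- c(G = 9e5, V = 9e4, A = 4e3, B = 2e3, C = 1.5e3, D = 5e2, E = 5e4)
  d <- idu_derivatives(s, r)
  leak <- sum(d$dstate) + unname(d$fluxes["deaths_overdose"] +
                                   d$fluxes["deaths_oat_transition"])
  # the -xi*V term removes xi*(V - B) extra persons from the books
  expect_equal(leak, -p$xi * (s[["V"]] - s[["B"]]), tolerance = 1e-9)
})

test_that("integration preserves equilibria and conserves population", {
  p <- mean_params()
  # beta = 0, tau = 0, no PWID: V/G balance is a fixed point
  r0 <- rate_set(p, beta = 0, gamma = 0.2, tau = 0, alpha = 0)
  G0 <- 1e6 / (1 + p$theta / (0.2 + p$mu_B))
  s0 <- c(G = G0, V = 1e6 - G0, A = 0, B = 0, C = 0, D = 0, E = 0)
  tr <- integrate_model(s0, r0, horizon = 50)
  expect_equal(tr$states[nrow(tr$states), ], s0, tolerance = 1e-7)

  # conservation along a perturbed PWID trajectory
  cal <- fixture_cal()
  s1 <- cal$state * c(1, 1.2, 2, 0.5, 1.5, 0.7, 1)
  tr1 <- integrate_model(s1, cal$rates, horizon = 10)
  n <- nrow(tr1$states)
  drop <- sum(tr1$states[n, ]) - sum(s1)
  leak <- tr1$cumflux[n, "deaths_overdose"] + tr1$cumflux[n, "deaths_oat_transition"]
  expect_lt(abs(drop + leak), 1e-6 * sum(s1))

  # cumulative fluxes are non-decreasing, states non-negative
  expect_true(all(diff(tr1$cumflux) >= -1e-9))
  expect_true(all(tr1$states >= 0))
})

test_that("solution is insensitive to the output grid", {
  cal <- fixture_cal()
  s1 <- cal$state * c(1, 1.1, 1.5, 0.8, 1.2, 0.9, 1)
  a <- integrate_model(s1, cal$rates, horizon = 10, output_step = 1 / 12)
  b <- integrate_model(s1, cal$rates, horizon = 10, output_step = 1 / 24)
  expect_equal(a$states[nrow(a$states), ], b$states[nrow(b$states), ],
               tolerance = 1e-8)
})

test_that("find_equilibrium matches closed forms and long-horizon integration", {
  p <- mean_params()
  r0 <- rate_set(p, beta = 0, gamma = 0.2, tau = 0, alpha = 0)
  s <- find_equilibrium(r0, N = 1e6)
  expect_equal(unname(s["V"] / s["G"]), p$theta / (0.2 + p$mu_B),
               tolerance = 1e-9)
  expect_true(all(s[c("A", "B", "C", "D", "E")] == 0))

  cal <- fixture_cal()
  s2 <- find_equilibrium(cal$rates)
  expect_equal(s2, cal$state, tolerance = 1e-6)
  # closed-system derivative norm at the steady state
  d <- idu_derivatives(s2, cal$rates)
  closed <- d$dstate
  closed["G"] <- closed["G"] + unname(d$fluxes["deaths_overdose"] +
                                        d$fluxes["deaths_oat_transition"])
  expect_lt(max(abs(closed)), 1e-9 * sum(s2) * 10)
  # the open system started at the steady state: V, A..E are stationary to
  # a fraction of the slow demographic drift, and the G-drift equals the
  # unreplaced death flux
  tr <- integrate_model(cal$state, cal$rates, horizon = 50, output_step = 1)
  send <- tr$states[nrow(tr$states), ]
  expect_equal(unname(send[2:7]), unname(cal$state[2:7]), tolerance = 5e-3)
  d0 <- idu_derivatives(cal$state, cal$rates)
  g_drift <- unname((tr$states[2, "G"] - tr$states[1, "G"]) /
                      diff(tr$times[1:2]))
  expect_equal(g_drift,
               -unname(d0$fluxes["deaths_overdose"] +
                         d0$fluxes["deaths_oat_transition"]),
               tolerance = 0.02)
})

test_that("OAT-neutral rates make the A/B vs C/D split irrelevant", {
  p <- mean_params()
  p$RR_OAT <- 1; p$RR_OATov <- 1; p$RR_OATin <- 1; p$RR_OATout <- 1
  r <- rate_set(p, beta = 0.4, gamma = 0.2, tau = 150, alpha = 0.5)
  s1 <- c(G = 9e5, V = 9e4, A = 4e3, B = 2e3, C = 1e3, D = 5e2, E = 5e4)
  s2 <- c(G = 9e5, V = 9e4, A = 2e3, B = 1e3, C = 3e3, D = 1.5e3, E = 5e4)
  f1 <- initiation_flux(s1, r); f2 <- initiation_flux(s2, r)
  expect_equal(f1$assisted, f2$assisted, tolerance = 1e-12)
  d1 <- idu_derivatives(s1, r); d2 <- idu_derivatives(s2, r)
  expect_equal(unname(d1$fluxes["deaths_overdose"]),
               unname(d2$fluxes["deaths_overdose"]), tolerance = 1e-12)
})

test_that("invalid states and horizons are rejected", {
  cal <- fixture_cal()
  expect_error(integrate_model(cal$state, cal$rates, horizon = -1), "horizon")
  bad <- cal$state; bad["V"] <- -5
  expect_error(integrate_model(bad, cal$rates, horizon = 1), ">= 0")
  expect_error(initiation_flux(c(G = 0, V = 0, A = 0, B = 0, C = 0, D = 0, E = 0),
                               cal$rates), "> 0")
})
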