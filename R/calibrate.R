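## Equilibrium calibration: for each sampled parameter set, solve for
## (beta, gamma, tau, alpha) so the baseline steady state hits the four
## sampled targets (non-IDU drug-use prevalence, PWID prevalence, proportion
## of initiations unassisted, OAT coverage).
##
## At a steady state the four PWID equations are linear and homogeneous in
## (A, B, C, D) once the unassisted flux is expressed as the target fraction
## of total initiations: existence of a positive stationary PWID profile is
## the Perron-root condition lambda_max(M(W, alpha)) = 0 on a 4x4 Metzler
## matrix, where W = beta*V/N. Calibration is therefore a nested
## one-dimensional root-find (W inside, alpha outside) followed by closed
## forms for gamma and tau -- exact where trajectory least squares would be
## approximate.

# PWID-block matrix under the calibration closure: total initiation inflow
# is phi * W * S with phi = 1/(1 - prop_unassisted) and S the RR-weighted
# PWID count.
calib_block <- function(p, W, alpha, phi, d) {
  o <- p$RR_OAT; w <- p$RR_I; m <- 1 / p$m_inv
  xi_oat <- if (!is.null(p$xi_oat)) p$xi_oat else p$xi
  outA <- m * W + alpha + p$xi + p$mu_B + p$mu_OV
  outB <- alpha + p$xi + p$mu_B + p$mu_OV
  outC <- p$rho + m * o * W + xi_oat + p$mu_B + p$RR_OATov * p$mu_OV
  outD <- p$rho + xi_oat + p$mu_B + p$RR_OATov * p$mu_OV
  matrix(c(
    phi * W - outA, phi * W * w, phi * W * o + p$rho * (1 - d$delta_exit), phi * W * w * o,
    m * W, -outB, 0, p$rho * (1 - d$delta_exit),
    alpha * (1 - d$delta_enter), 0, -outC, 0,
    0, alpha * (1 - d$delta_enter), m * o * W, -outD
  ), 4, 4, byrow = TRUE)
}

# dominant (Perron) eigenvalue and eigenvector of a Metzler matrix
perron <- function(M) {
  e <- eigen(M)
  i <- which.max(Re(e$values))
  x <- Re(e$vectors[, i])
  if (sum(x) < 0) x <- -x
  list(lambda = Re(e$values[i]), x = x)
}

# W such that lambda_max(M(W, alpha)) = 0: safeguarded Newton with
# finite-difference derivative, bisection fallback.
solve_W <- function(p, alpha, phi, d, W0 = NULL) {
  lam <- function(W) perron(calib_block(p, W, alpha, phi, d))$lambda
  lo <- 0; flo <- lam(0)
  hi <- if (is.null(W0)) 0.1 else 2 * W0
  fhi <- lam(hi)
  for (i in 1:60) {
    if (fhi > 0) break
    lo <- hi; flo <- fhi
    hi <- hi * 2; fhi <- lam(hi)
  }
  if (fhi < 0) stop("calibration: PWID block cannot reach criticality")
  W <- if (!is.null(W0) && W0 > lo && W0 < hi) W0 else 0.5 * (lo + hi)
  f <- lam(W)
  for (i in 1:100) {
    if (abs(f) < 1e-13) break
    if (f > 0) { hi <- W; fhi <- f } else { lo <- W; flo <- f }
    h <- max(1e-8, 1e-6 * W)
    df <- (lam(W + h) - f) / h
    Wn <- if (is.finite(df) && df > 0) W - f / df else NA
    if (!is.finite(Wn) || Wn <= lo || Wn >= hi) Wn <- 0.5 * (lo + hi)
    W <- Wn
    f <- lam(W)
    if (hi - lo < 1e-15 * max(1, W)) break
  }
  W
}

#' Calibration observables of a model state
#'
#' The four quantities the model is calibrated to: prevalence of non-IDU
#' illicit drug use `V/N`, PWID prevalence `(A+B+C+D)/N`, the proportion of
#' IDU initiations that are self-initiated, and OAT coverage among PWID
#' `(C+D)/(A+B+C+D)`.
#'
#' @param s Compartment state.
#' @param r An `idu_rates` object.
#' @return Named list `prev_nonIDU`, `prev_PWID`, `prop_unassisted`,
#'   `oat_coverage`.
#' @export
observables <- function(s, r) {
  s <- as_state(s)
  N <- sum(s)
  P <- sum(s[c("A", "B", "C", "D")])
  if (P <= 0) stop("OAT coverage undefined: no PWID in state")
  fl <- initiation_flux(s, r)
  tot <- fl$assisted + fl$unassisted
  list(
    prev_nonIDU = unname(s["V"] / N),
    prev_PWID = unname(P / N),
    prop_unassisted = if (tot > 0) fl$unassisted / tot else NA_real_,
    oat_coverage = unname(sum(s[c("C", "D")]) / P)
  )
}

#' Calibrate one parameter set to its sampled targets
#'
#' Solves for `(beta, gamma, tau, alpha)` such that the baseline steady
#' state (see [find_equilibrium()]) reproduces the set's four calibration
#' targets exactly. The solution is semi-analytic: a nested root-find on
#' (W, alpha) through the Perron root of the stationary PWID block, then
#' closed-form `gamma` and `tau`.
#'
#' @param p One-row parameter set (row of [sample_parameter_sets()]).
#' @param N0 Population scale (default 1e6, matching per-million reporting).
#' @param tau_vmin,literal_dB Passed to [rate_set()].
#' @return Object of class `idu_calibration`: list with `params` (the input
#'   row), `rates` (full `idu_rates`), `state` (equilibrium), `observables`,
#'   `residual` (max absolute target error), `converged`.
#' @examples
#' p <- sample_parameter_sets(1, seed = 42)
#' cal <- calibrate_parameter_set(p[1, ])
#' cal$observables$oat_coverage - p$target_oat_coverage
#' @export
calibrate_parameter_set <- function(p, N0 = 1e6, tau_vmin = 1,
                                    literal_dB = FALSE) {
  p <- as.list(p)
  d <- excess_overdose_fractions(p)
  u <- p$target_prop_unassisted
  cstar <- p$target_oat_coverage
  phi <- 1 / (1 - u)
  xi_oat <- if (!is.null(p$xi_oat)) p$xi_oat else p$xi

  fail <- function(msg) {
    structure(list(params = p, rates = NULL, state = NULL, observables = NULL,
                   residual = Inf, converged = FALSE, message = msg),
              class = "idu_calibration")
  }

  # coverage of the stationary PWID profile as a function of alpha
  Wlast <- NULL
  profile <- function(alpha) {
    W <- solve_W(p, alpha, phi, d, W0 = Wlast)
    Wlast <<- W
    pr <- perron(calib_block(p, W, alpha, phi, d))
    x <- pmax(pr$x, 0)
    x <- x / sum(x)
    list(W = W, x = x, coverage = x[3] + x[4])
  }
  gfun <- function(alpha) profile(alpha)$coverage - cstar

  res <- try({
    # initial guess and bracket for alpha from the coverage balance
    a0 <- cstar / (1 - cstar) * (p$rho + xi_oat + p$mu_B + p$RR_OATov * p$mu_OV)
    lo <- 1e-10; hi <- max(2 * a0, 0.1)
    for (i in 1:60) {
      if (gfun(hi) > 0) break
      hi <- hi * 2
    }
    alpha <- uniroot(gfun, c(lo, hi), tol = 1e-11)$root
    pro <- profile(alpha)

    V <- p$target_prev_nonIDU * N0
    P <- p$target_prev_PWID * N0
    x <- pro$x * P
    beta <- pro$W * N0 / V
    S <- sum(x * c(1, p$RR_I, p$RR_OAT, p$RR_I * p$RR_OAT))
    assisted <- pro$W * S
    tau <- u / (1 - u) * assisted
    E <- (p$xi * (x[1] + x[2]) + xi_oat * (x[3] + x[4])) / p$mu_B
    G <- N0 - V - P - E
    if (G <= 0) stop("infeasible: equilibrium G <= 0")
    gamma <- (p$theta * G - phi * pro$W * S - p$mu_B * V) / V
    if (gamma < 0) stop("infeasible: negative gamma")
    r <- rate_set(p, beta = beta, gamma = gamma, tau = tau, alpha = alpha,
                  tau_vmin = tau_vmin, literal_dB = literal_dB)
    s <- setNames(c(G, V, x, E), state_names)
    obs <- observables(s, r)
    resid <- max(abs(c(
      obs$prev_nonIDU - p$target_prev_nonIDU,
      obs$prev_PWID - p$target_prev_PWID,
      obs$prop_unassisted - u,
      obs$oat_coverage - cstar
    )))
    structure(list(params = p, rates = r, state = s, observables = obs,
                   residual = resid, converged = resid < 1e-6,
                   message = "ok"),
              class = "idu_calibration")
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    return(fail(conditionMessage(attr(res, "condition"))))
  }
  res
}

#' Calibrate every row of a parameter table
#'
#' @param params Parameter table from [sample_parameter_sets()].
#' @param N0 Population scale.
#' @param ... Passed to [calibrate_parameter_set()].
#' @return List of `idu_calibration` objects, one per row.
#' @export
calibrate_sets <- function(params, N0 = 1e6, ...) {
  lapply(seq_len(nrow(params)), function(i) {
    calibrate_parameter_set(params[i, ], N0 = N0, ...)
  })
}

#' @export
print.idu_calibration <- function(x, ...) {
  if (!x$converged) {
    cat("<idu_calibration> NOT converged:", x$message, "\n")
  } else {
    cat("<idu_calibration> converged; residual", format(x$residual, digits = 3), "\n")
    cat(sprintf("  beta=%.4g gamma=%.4g tau=%.4g alpha=%.4g\n",
                x$rates$beta, x$rates$gamma, x$rates$tau, x$rates$alpha))
  }
  invisible(x)
}

#' Export a list of calibrations as a flat table
#'
#' @param cals List of `idu_calibration` objects from [calibrate_sets()].
#' @return `data.frame` with sampled inputs, fitted rates, residuals and the
#'   convergence flag (fitted columns `NA` where calibration failed).
#' @export
calibration_table <- function(cals) {
  rows <- lapply(cals, function(cl) {
    base <- as.data.frame(cl$params)
    if (cl$converged) {
      cbind(base, beta = cl$rates$beta, gamma = cl$rates$gamma,
            tau = cl$rates$tau, alpha = cl$rates$alpha,
            residual = cl$residual, converged = TRUE)
    } else {
      cbind(base, beta = NA_real_, gamma = NA_real_, tau = NA_real_,
            alpha = NA_real_, residual = NA_real_, converged = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' OAT enrollment rate achieving a target equilibrium coverage
#'
#' With `beta`, `gamma`, `tau` held at their calibrated values, solves for
#' the enrollment rate `alpha` whose *new* steady state has the requested
#' OAT coverage among PWID. Scale-up is thus read as sustained coverage
#' (the enrollment rate jumps at t = 0 and the system relaxes towards the
#' new coverage), not an instantaneous re-proportioning of the PWID pool.
#'
#' @param cal A converged `idu_calibration`.
#' @param coverage Target coverage in `[0, 1)`.
#' @param N0 Population scale used at calibration.
#' @return The enrollment rate `alpha` (per year).
#' @export
alpha_for_coverage <- function(cal, coverage, N0 = 1e6) {
  stopifnot(inherits(cal, "idu_calibration"), cal$converged)
  if (coverage < 0 || coverage >= 1) stop("`coverage` must be in [0, 1)")
  if (coverage == 0) return(0)
  r <- cal$rates
  Vlast <- unname(cal$state["V"])
  cov_of_alpha <- function(a) {
    r2 <- r
    r2$alpha <- a
    s <- find_equilibrium(r2, N = N0, V0 = Vlast)
    Vlast <<- unname(s["V"])
    unname(sum(s[c("C", "D")]) / sum(s[c("A", "B", "C", "D")]))
  }
  g <- function(a) cov_of_alpha(a) - coverage
  # coverage balance gives alpha ~ k * c/(1-c); scale from the calibrated
  # baseline pair to seed a tight bracket
  cb <- cal$observables$oat_coverage
  a0 <- r$alpha * (coverage / (1 - coverage)) / (cb / (1 - cb))
  lo <- a0 / 1.6
  hi <- a0 * 1.6
  glo <- g(lo)
  for (i in 1:80) {
    if (glo < 0) break
    hi <- lo
    lo <- lo / 2
    glo <- g(lo)
  }
  ghi <- g(hi)
  for (i in 1:80) {
    if (ghi > 0) break
    lo <- hi
    glo <- ghi
    hi <- hi * 2
    ghi <- g(hi)
  }
  if (ghi < 0) stop("requested coverage unreachable")
  uniroot(g, c(lo, hi), f.lower = glo, f.upper = ghi, tol = 1e-7)$root
}
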