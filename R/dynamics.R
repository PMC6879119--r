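## Seven-compartment dynamics: rate-set container, the initiation force,
## the ODE right-hand side, trajectory integration, and steady states.
##
## Compartments: G (no illicit drug use excluding cannabis), V (illicit drug
## use, injection-naive), A/B (PWID without/with assisting history, not on
## OAT), C/D (same, on OAT), E (former PWID). All rates are per person-year;
## time is in years.

state_names <- c("G", "V", "A", "B", "C", "D", "E")
flux_names <- c(
  "assisted_init", "unassisted_init", "hist_AB", "hist_CD",
  "oat_entries", "oat_exits", "cessations", "deaths_baseline",
  "deaths_overdose", "deaths_oat_transition"
)

#' Excess overdose-death fractions at OAT entry and exit
#'
#' The first four weeks after entering or leaving OAT carry excess overdose
#' risk. This is modelled as a one-off death probability applied to the
#' entry/exit flow: `delta_exit = mu_OV * (RR_OATout - 1) * 4/52` and
#' `delta_enter = mu_OV * RR_OATov * (RR_OATin - 1) * 4/52`. Negative values
#' (a protective RR draw below 1) are clipped to zero.
#'
#' @param p One-row parameter set (list or data.frame row) with `mu_OV`,
#'   `RR_OATout`, `RR_OATin`, `RR_OATov`.
#' @return Named list with `delta_enter` and `delta_exit`, both in `[0, 1)`.
#' @examples
#' excess_overdose_fractions(
#'   list(mu_OV = 0.0062, RR_OATout = 2.43, RR_OATin = 2.10, RR_OATov = 0.21)
#' )
#' @export
excess_overdose_fractions <- function(p) {
  frac <- 4 / 52
  list(
    delta_enter = max(0, p$mu_OV * p$RR_OATov * (p$RR_OATin - 1) * frac),
    delta_exit = max(0, p$mu_OV * (p$RR_OATout - 1) * frac)
  )
}

#' Assemble a full rate set for the dynamic model
#'
#' Combines a sampled parameter set with the four calibrated rates and the
#' derived OAT-transition death fractions into the flat container consumed
#' by [idu_derivatives()], [integrate_model()] and [find_equilibrium()].
#'
#' @param p One-row parameter set (e.g. a row of [sample_parameter_sets()]).
#' @param beta IDU initiation transmission coefficient (per year).
#' @param gamma Rate at which injection-naive drug users cease use (per year).
#' @param tau Number of unassisted IDU initiations per year.
#' @param alpha OAT enrollment rate (per year).
#' @param tau_vmin Throttle scale (persons): the unassisted flux is
#'   `tau * min(1, V / tau_vmin)` so `tau` can never drive `V` negative. At
#'   calibrated states `V` exceeds this by orders of magnitude and the
#'   throttle is inactive.
#' @param literal_dB If `TRUE`, use the published `-xi*V` cessation term in
#'   dB/dt verbatim (breaks the conservation identity; kept for
#'   inspection). Default `FALSE` applies `-xi*B`.
#' @return Object of class `idu_rates`.
#' @export
rate_set <- function(p, beta, gamma, tau, alpha, tau_vmin = 1,
                     literal_dB = FALSE) {
  stopifnot(beta >= 0, gamma >= 0, tau >= 0, alpha >= 0)
  d <- excess_overdose_fractions(p)
  xi_oat <- if (!is.null(p$xi_oat)) p$xi_oat else p$xi
  r <- list(
    mu_B = p$mu_B, mu_OV = p$mu_OV, theta = p$theta, xi = p$xi,
    xi_oat = xi_oat, rho = p$rho, m = 1 / p$m_inv, RR_I = p$RR_I,
    RR_OAT = p$RR_OAT, RR_OATov = p$RR_OATov,
    beta = beta, gamma = gamma, tau = tau, alpha = alpha,
    delta_enter = d$delta_enter, delta_exit = d$delta_exit,
    tau_vmin = tau_vmin, literal_dB = isTRUE(literal_dB)
  )
  stopifnot(r$delta_enter >= 0, r$delta_enter < 1,
            r$delta_exit >= 0, r$delta_exit < 1)
  structure(r, class = "idu_rates")
}

# flat numeric vector in the order the C++ right-hand side expects
rate_vector <- function(r) {
  c(r$mu_B, r$mu_OV, r$theta, r$xi, r$xi_oat, r$rho, r$m, r$RR_I, r$RR_OAT,
    r$RR_OATov, r$beta, r$gamma, r$tau, r$alpha, r$delta_enter, r$delta_exit,
    r$tau_vmin, as.numeric(r$literal_dB))
}

as_state <- function(s) {
  s <- unlist(s)[state_names]
  if (any(is.na(s))) stop("state must provide components ", paste(state_names, collapse = ", "))
  if (any(s < 0)) stop("state components must be >= 0")
  if (sum(s) <= 0) stop("total population must be > 0")
  s
}

#' Instantaneous IDU initiation fluxes
#'
#' The assisted flux is a prevalence-proportional force of initiation acting
#' on the injection-naive drug-using population:
#' `beta * (A + RR_I*B + RR_OAT*C + RR_I*RR_OAT*D) / N * V`. The unassisted
#' flux is the fixed count `tau` per year, throttled only when `V` is
#' essentially exhausted.
#'
#' @param s Compartment state (named vector or list with `G`..`E`).
#' @param r An `idu_rates` object.
#' @return Named list with `assisted` and `unassisted` rates (persons/year).
#' @export
initiation_flux <- function(s, r) {
  s <- as_state(s)
  N <- sum(s)
  force <- r$beta * (s["A"] + r$RR_I * s["B"] + r$RR_OAT * s["C"] +
                       r$RR_I * r$RR_OAT * s["D"]) / N
  list(
    assisted = unname(force * s["V"]),
    unassisted = r$tau * min(1, max(0, unname(s["V"]) / r$tau_vmin))
  )
}

#' Model right-hand side: compartment derivatives and event fluxes
#'
#' Pure-R reference implementation of the seven model equations (the
#' compiled integrator carries an equivalent copy). Births enter G at rate
#' `sigma = mu_B * N`, replacing all deaths except overdoses and the
#' OAT-transition excess deaths, so that
#' `dN/dt = -(overdose deaths + OAT-transition excess deaths)` identically.
#'
#' @param s Compartment state (named, components `G`..`E`).
#' @param r An `idu_rates` object.
#' @return List with `dstate` (named derivatives, persons/year) and `fluxes`
#'   (named instantaneous event rates).
#' @export
idu_derivatives <- function(s, r) {
  s <- as_state(s)
  G <- unname(s["G"]); V <- unname(s["V"]); A <- unname(s["A"])
  B <- unname(s["B"]); C <- unname(s["C"]); D <- unname(s["D"])
  E <- unname(s["E"])
  N <- sum(s)
  fl <- initiation_flux(s, r)
  assisted <- fl$assisted
  unassisted <- fl$unassisted
  gAB <- r$m * r$beta * A / N * V
  gCD <- r$m * r$beta * r$RR_OAT * C / N * V
  sigma <- r$mu_B * N
  cessB <- if (r$literal_dB) r$xi * V else r$xi * B
  cessE <- r$xi * (A + B) + r$xi_oat * (C + D)
  dx <- r$delta_exit; de <- r$delta_enter
  dstate <- c(
    G = sigma - r$theta * G + r$gamma * V - r$mu_B * G,
    V = r$theta * G - r$gamma * V - assisted - unassisted - r$mu_B * V,
    A = assisted + unassisted - gAB - r$alpha * A + r$rho * C * (1 - dx) -
      r$xi * A - (r$mu_B + r$mu_OV) * A,
    B = gAB - r$alpha * B + r$rho * D * (1 - dx) - cessB -
      (r$mu_B + r$mu_OV) * B,
    C = r$alpha * A * (1 - de) - r$rho * C - gCD - r$xi_oat * C -
      (r$mu_B + r$RR_OATov * r$mu_OV) * C,
    D = r$alpha * B * (1 - de) + gCD - r$rho * D - r$xi_oat * D -
      (r$mu_B + r$RR_OATov * r$mu_OV) * D,
    E = cessE - r$mu_B * E
  )
  fluxes <- c(
    assisted_init = assisted, unassisted_init = unassisted,
    hist_AB = unname(gAB), hist_CD = unname(gCD),
    oat_entries = unname(r$alpha * (A + B)),
    oat_exits = unname(r$rho * (C + D)),
    cessations = unname(cessE),
    deaths_baseline = unname(sigma),
    deaths_overdose = unname(r$mu_OV * (A + B) + r$RR_OATov * r$mu_OV * (C + D)),
    deaths_oat_transition = unname(de * r$alpha * (A + B) + dx * r$rho * (C + D))
  )
  list(dstate = dstate, fluxes = fluxes)
}

#' Integrate the model over a time horizon
#'
#' Adaptive Dormand-Prince 5(4) integration with cumulative event-flux
#' accounting. Compartments dipping below zero by less than `neg_tol` are
#' clamped to zero; larger negativity aborts with an error.
#'
#' @param s0 Initial compartment state (named, components `G`..`E`).
#' @param r An `idu_rates` object.
#' @param horizon Years to integrate (> 0).
#' @param output_step Output grid spacing in years (default monthly).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param neg_tol Negativity clamp threshold (persons).
#' @return Object of class `idu_trajectory`: list with `times`, `states`
#'   (matrix, one row per time), and `cumflux` (matrix of cumulative event
#'   counts since time 0).
#' @export
integrate_model <- function(s0, r, horizon, output_step = 1 / 12,
                            rtol = 1e-8, atol = NULL, neg_tol = NULL) {
  if (horizon <= 0) stop("`horizon` must be > 0")
  s0 <- as_state(s0)
  N0 <- sum(s0)
  if (is.null(atol)) atol <- 1e-8 * N0
  if (is.null(neg_tol)) neg_tol <- 1e-9 * N0
  times <- unique(c(seq(0, horizon, by = output_step), horizon))
  out <- .rk45_idu(unname(s0), rate_vector(r), times, rtol, atol, neg_tol)
  states <- out[, 2:8, drop = FALSE]
  colnames(states) <- state_names
  cumflux <- out[, 9:18, drop = FALSE]
  colnames(cumflux) <- flux_names
  structure(list(times = out[, 1], states = states, cumflux = cumflux),
            class = "idu_trajectory")
}

#' @export
print.idu_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("<idu_trajectory> ", n, " time points over ", x$times[n], " years\n", sep = "")
  cat("  final state:", paste(sprintf("%s=%.1f", state_names, x$states[n, ]),
                              collapse = " "), "\n")
  invisible(x)
}

#' Export a trajectory as tidy data frames
#'
#' @param x An `idu_trajectory`.
#' @return List of two data frames: `states` (time, compartment, value) and
#'   `fluxes` (time, flux, cumulative).
#' @export
trajectory_tidy <- function(x) {
  stopifnot(inherits(x, "idu_trajectory"))
  nt <- length(x$times)
  states <- data.frame(
    time = rep(x$times, times = 7),
    compartment = rep(state_names, each = nt),
    value = as.vector(x$states)
  )
  fluxes <- data.frame(
    time = rep(x$times, times = 10),
    flux = rep(flux_names, each = nt),
    cumulative = as.vector(x$cumflux)
  )
  list(states = states, fluxes = fluxes)
}

# Solve the PWID block (A,B,C,D) at stationarity for *fixed* tau:
# the four equations are linear in (A,B,C,D) given W = beta*V/N.
# Returns NULL when the block is super-critical (no finite positive state).
pwid_block_solve <- function(r, W, tau) {
  o <- r$RR_OAT; w <- r$RR_I; m <- r$m
  de <- r$delta_enter; dx <- r$delta_exit
  outA <- m * W + r$alpha + r$xi + r$mu_B + r$mu_OV
  outB <- r$alpha + r$xi + r$mu_B + r$mu_OV
  outC <- r$rho + m * o * W + r$xi_oat + r$mu_B + r$RR_OATov * r$mu_OV
  outD <- r$rho + r$xi_oat + r$mu_B + r$RR_OATov * r$mu_OV
  K <- matrix(c(
    W - outA, W * w, W * o + r$rho * (1 - dx), W * w * o,
    m * W, -outB, 0, r$rho * (1 - dx),
    r$alpha * (1 - de), 0, -outC, 0,
    0, r$alpha * (1 - de), m * o * W, -outD
  ), 4, 4, byrow = TRUE)
  x <- tryCatch(solve(K, c(-tau, 0, 0, 0)), error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x)) || any(x < 0)) return(NULL)
  x
}

#' Baseline steady state of the model for a given rate set
#'
#' Because births replace only non-overdose deaths, the open system has no
#' exact fixed point with PWID present (total population declines at the
#' overdose death rate, of order `1e-4 * N` per year). The steady state is
#' therefore defined on the demographically closed variant in which overdose
#' and OAT-transition deaths are also replaced into G. At the returned
#' state, the derivatives of V, A, B, C, D and E under the *open* model are
#' zero to solver precision; only G carries the slow demographic drift.
#'
#' @param r An `idu_rates` object.
#' @param N Population scale (total population at the steady state).
#' @param V0 Optional warm start for the injection-naive drug-using
#'   compartment V (e.g. from a nearby rate set); falls back to the full
#'   bracket when the local bracket fails.
#' @return Named compartment state vector.
#' @export
find_equilibrium <- function(r, N = 1e6, V0 = NULL) {
  state_of_V <- function(V) {
    W <- r$beta * V / N
    x <- pwid_block_solve(r, W, r$tau)
    if (is.null(x)) return(NULL)
    P <- sum(x)
    E <- (r$xi * (x[1] + x[2]) + r$xi_oat * (x[3] + x[4])) / r$mu_B
    G <- N - V - P - E
    if (G < 0) return(NULL)
    setNames(c(G, V, x[1], x[2], x[3], x[4], E), state_names)
  }
  # residual of dV/dt = 0 at the V-parameterized stationary profile.
  # Infeasible V (super-critical PWID block, or G < 0) always lies above the
  # root, so it is mapped to a large negative value to keep Brent bracketing.
  resid <- function(V) {
    s <- state_of_V(V)
    if (is.null(s)) return(-1e12)
    W <- r$beta * V / N
    S <- s["A"] + r$RR_I * s["B"] + r$RR_OAT * s["C"] + r$RR_I * r$RR_OAT * s["D"]
    unname(r$theta * s["G"] - r$gamma * V - W * S - r$tau - r$mu_B * V)
  }
  lo <- max(1e-9 * N, 1e-6)
  hi <- 0.999 * N
  if (!is.null(V0) && is.finite(V0) && V0 > lo && V0 < hi) {
    l2 <- 0.85 * V0
    h2 <- min(hi, 1.18 * V0)
    if (resid(l2) > 0 && resid(h2) < 0) {
      lo <- l2
      hi <- h2
    }
  }
  if (resid(lo) < 0 || resid(hi) > 0) {
    stop("find_equilibrium: could not bracket the steady state; rates may be infeasible")
  }
  V <- uniroot(resid, c(lo, hi), tol = 1e-7 * N)$root
  # Newton polish so the dV residual is at solver precision
  for (i in 1:3) {
    f0 <- resid(V)
    if (abs(f0) < 1e-10 * N) break
    h <- 1e-7 * V
    df <- (resid(V + h) - f0) / h
    if (!is.finite(df) || df == 0) break
    Vn <- V - f0 / df
    if (Vn > 0 && is.finite(Vn) && abs(resid(Vn)) < abs(f0)) V <- Vn else break
  }
  s <- state_of_V(V)
  # polish + verify: closed-system derivative norm
  d <- idu_derivatives(s, r)
  closed <- d$dstate
  closed["G"] <- closed["G"] + d$fluxes["deaths_overdose"] +
    d$fluxes["deaths_oat_transition"]
  if (max(abs(closed)) > 1e-7 * N) {
    stop("find_equilibrium: residual derivative norm ", max(abs(closed)),
         " exceeds tolerance")
  }
  s
}
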