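## Scenario projection: baseline and OAT scale-up runs over a 10-year
## horizon, annual outcome extraction, and Monte Carlo uncertainty
## summaries across calibrated parameter sets.

#' Percent reduction of a scenario outcome relative to baseline
#'
#' @param baseline_value Baseline outcome (> 0).
#' @param scenario_value Scenario outcome.
#' @return `100 * (baseline - scenario) / baseline`.
#' @export
relative_reduction <- function(baseline_value, scenario_value) {
  if (any(baseline_value <= 0)) stop("baseline value must be > 0")
  100 * (baseline_value - scenario_value) / baseline_value
}

# annual outcome series from a trajectory with a grid containing integer years
annual_outcomes <- function(traj, years) {
  yr_idx <- vapply(0:years, function(y) which.min(abs(traj$times - y)), 1L)
  tot_init <- traj$cumflux[, "assisted_init"] + traj$cumflux[, "unassisted_init"]
  pwid <- rowSums(traj$states[, c("A", "B", "C", "D"), drop = FALSE])
  data.frame(
    year = 1:years,
    assisted = diff(traj$cumflux[yr_idx, "assisted_init"]),
    unassisted = diff(traj$cumflux[yr_idx, "unassisted_init"]),
    total = diff(tot_init[yr_idx]),
    pwid_size = pwid[yr_idx][-1]
  )
}

#' Run one scenario for a calibrated parameter set
#'
#' Starts from the calibrated baseline steady state. For a coverage target,
#' the enrollment rate is replaced at t = 0 by [alpha_for_coverage()];
#' `"baseline"` keeps the calibrated rate. Annual initiations are integrals
#' of the initiation flux over each year `(k-1, k]`; PWID population size is
#' read at each year's end.
#'
#' @param cal A converged `idu_calibration`.
#' @param coverage `"baseline"` or a coverage fraction in `[0, 1)`.
#' @param years Projection horizon in years.
#' @param baseline Optional precomputed baseline `idu_scenario` for the same
#'   calibration, to avoid re-running it; computed on demand otherwise.
#' @param N0 Population scale used at calibration.
#' @return Object of class `idu_scenario`: annual series of assisted,
#'   unassisted and total initiations and PWID size, plus relative
#'   reductions versus the same set's baseline run.
#' @export
run_scenario <- function(cal, coverage = "baseline", years = 10,
                         baseline = NULL, N0 = 1e6) {
  stopifnot(inherits(cal, "idu_calibration"))
  if (!cal$converged) stop("calibration did not converge; cannot run scenario")
  is_base <- identical(coverage, "baseline")
  r <- cal$rates
  if (!is_base) {
    r$alpha <- alpha_for_coverage(cal, coverage, N0 = N0)
  }
  traj <- integrate_model(cal$state, r, horizon = years)
  ann <- annual_outcomes(traj, years)
  if (is_base) {
    base_ann <- ann
  } else {
    if (is.null(baseline)) {
      baseline <- run_scenario(cal, "baseline", years = years, N0 = N0)
    }
    stopifnot(inherits(baseline, "idu_scenario"))
    base_ann <- baseline$annual
  }
  red <- data.frame(
    year = ann$year,
    initiations = relative_reduction(base_ann$total, ann$total),
    pwid_size = relative_reduction(base_ann$pwid_size, ann$pwid_size)
  )
  structure(list(coverage = if (is_base) "baseline" else coverage,
                 alpha = r$alpha, annual = ann, reduction = red,
                 trajectory = traj),
            class = "idu_scenario")
}

#' @export
print.idu_scenario <- function(x, ...) {
  n <- nrow(x$annual)
  cat("<idu_scenario> coverage:", format(x$coverage),
      " year-", n, " initiations: ", round(x$annual$total[n], 1),
      " (reduction ", round(x$reduction$initiations[n], 2), "%)\n", sep = "")
  invisible(x)
}

#' Monte Carlo uncertainty analysis of OAT scale-up
#'
#' Samples `n_sets` parameter sets, calibrates each to its own targets, and
#' runs the baseline plus each coverage scale-up scenario, collecting annual
#' outcomes and per-set relative reductions. Summaries are means with
#' 2.5--97.5 percentile intervals across converged sets (reductions are
#' averaged per set, i.e. mean-of-ratios).
#'
#' @param n_sets Number of parameter sets (>= 1; >= 100 recommended).
#' @param seed Integer seed.
#' @param coverages Vector of coverage targets in `[0, 1)`.
#' @param years Horizon in years.
#' @param N0 Population scale.
#' @param param_table Optional pre-built parameter table (e.g. with a
#'   sensitivity override applied); when supplied, `n_sets` and `seed` are
#'   ignored for sampling.
#' @param distributions Optional distribution overrides for sampling (see
#'   [sample_parameter_sets()]).
#' @param progress Print a progress line every 200 sets.
#' @return Object of class `idu_uncertainty` with elements `params`,
#'   `calibrations`, `baseline_equilibrium` (per-set annual equilibrium
#'   fluxes), `per_set` (long data frame of year-`years` outcomes),
#'   `summary`, `n_converged`, `seed`.
#' @export
uncertainty_analysis <- function(n_sets = 1000, seed = 1,
                                 coverages = c(0.4, 0.5, 0.6), years = 10,
                                 N0 = 1e6, param_table = NULL,
                                 distributions = NULL, progress = FALSE) {
  params <- if (is.null(param_table)) {
    sample_parameter_sets(n_sets, seed, distributions = distributions)
  } else {
    validate_parameter_sets(param_table)
  }
  n <- nrow(params)
  cals <- vector("list", n)
  eq_rows <- vector("list", n)
  per_set <- vector("list", n)
  for (i in seq_len(n)) {
    if (progress && i %% 200 == 0) message("  set ", i, "/", n)
    cal <- calibrate_parameter_set(params[i, ], N0 = N0)
    cals[[i]] <- cal
    if (!cal$converged) next
    fl <- initiation_flux(cal$state, cal$rates)
    eq_rows[[i]] <- data.frame(
      set = i, assisted = fl$assisted, unassisted = fl$unassisted,
      total = fl$assisted + fl$unassisted,
      pwid_size = sum(cal$state[c("A", "B", "C", "D")])
    )
    base <- run_scenario(cal, "baseline", years = years, N0 = N0)
    rows <- lapply(coverages, function(cv) {
      sc <- run_scenario(cal, cv, years = years, baseline = base, N0 = N0)
      data.frame(
        set = i, coverage = cv,
        total_init = sc$annual$total[years],
        pwid_size = sc$annual$pwid_size[years],
        red_init = sc$reduction$initiations[years],
        red_pwid = sc$reduction$pwid_size[years],
        base_init = base$annual$total[years],
        base_pwid = base$annual$pwid_size[years]
      )
    })
    per_set[[i]] <- do.call(rbind, rows)
  }
  conv <- vapply(cals, function(cl) cl$converged, logical(1))
  if (mean(conv) < 0.5) stop("fewer than 50% of parameter sets calibrated")
  per_set <- do.call(rbind, per_set)
  eqdf <- do.call(rbind, eq_rows)

  msum <- function(x) c(mean = mean(x), q2.5 = unname(quantile(x, 0.025)),
                        q97.5 = unname(quantile(x, 0.975)))
  summ <- do.call(rbind, lapply(coverages, function(cv) {
    d <- per_set[per_set$coverage == cv, ]
    data.frame(
      coverage = cv,
      rbind(
        data.frame(outcome = "total_initiations", t(msum(d$total_init))),
        data.frame(outcome = "pwid_size", t(msum(d$pwid_size))),
        data.frame(outcome = "reduction_initiations", t(msum(d$red_init))),
        data.frame(outcome = "reduction_pwid_size", t(msum(d$red_pwid)))
      )
    )
  }))
  base_sum <- rbind(
    data.frame(coverage = NA, outcome = "baseline_total_initiations",
               t(msum(eqdf$total))),
    data.frame(coverage = NA, outcome = "baseline_assisted_initiations",
               t(msum(eqdf$assisted))),
    data.frame(coverage = NA, outcome = "baseline_unassisted_initiations",
               t(msum(eqdf$unassisted))),
    data.frame(coverage = NA, outcome = "baseline_pwid_size",
               t(msum(eqdf$pwid_size)))
  )
  structure(list(
    params = params, calibrations = cals, baseline_equilibrium = eqdf,
    per_set = per_set, summary = rbind(base_sum, summ),
    n_converged = sum(conv), n_sets = n, seed = seed, years = years,
    coverages = coverages
  ), class = "idu_uncertainty")
}

#' @export
print.idu_uncertainty <- function(x, ...) {
  cat("<idu_uncertainty> ", x$n_converged, "/", x$n_sets,
      " sets converged; year ", x$years, " summaries:\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
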