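## Sensitivity machinery: partial rank correlation coefficients over the
## sampled parameter space, and the nine preset one-way analyses run
## against the 60% OAT scale-up scenario with common random numbers.

#' Partial rank correlation coefficients
#'
#' Rank-transforms every input column and the output, then for each input
#' correlates the residuals of rank-regressions of that input and of the
#' output on all remaining inputs. Constant columns yield `NA` with a
#' warning.
#'
#' @param inputs Numeric matrix or data frame, one row per model run, one
#'   column per sampled parameter.
#' @param output Numeric vector of the model outcome, aligned with rows.
#' @return `data.frame` with columns `parameter` and `prcc`, carrying
#'   attribute `n_sets`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(500), ncol = 5)
#' y <- 2 * x[, 1] + rnorm(100, sd = 0.1)
#' prcc(x, y)
#' @export
prcc <- function(inputs, output) {
  X <- as.matrix(inputs)
  if (!is.numeric(X)) stop("`inputs` must be numeric")
  n <- nrow(X); k <- ncol(X)
  if (length(output) != n) stop("`output` must align with rows of `inputs`")
  if (n < k + 2) stop("need at least ncol(inputs) + 2 runs")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  Xr <- apply(X, 2, rank)
  yr <- rank(output)
  out <- vapply(seq_len(k), function(j) {
    if (length(unique(X[, j])) < 2) {
      warning("constant input column: ", colnames(X)[j])
      return(NA_real_)
    }
    Z <- cbind(1, Xr[, -j, drop = FALSE])
    qz <- qr(Z)
    r1 <- qr.resid(qz, Xr[, j])
    r2 <- qr.resid(qz, yr)
    if (sd(r1) == 0 || sd(r2) == 0) return(NA_real_)
    cor(r1, r2)
  }, numeric(1))
  res <- data.frame(parameter = colnames(X), prcc = out)
  attr(res, "n_sets") <- n
  res
}

#' PRCC of sampled parameters against scale-up impact
#'
#' Convenience wrapper computing PRCCs of every sampled (non-fixed)
#' parameter against the year-10 relative reduction in IDU initiations for
#' a given coverage scenario of an [uncertainty_analysis()] result.
#'
#' @param ua An `idu_uncertainty` object.
#' @param coverage Which scenario's reduction to use (default 0.6).
#' @return As [prcc()].
#' @export
prcc_scaleup <- function(ua, coverage = 0.6) {
  stopifnot(inherits(ua, "idu_uncertainty"))
  d <- ua$per_set[ua$per_set$coverage == coverage, ]
  if (!nrow(d)) stop("coverage ", coverage, " not present in the analysis")
  sampled <- setdiff(names(ua$params), c("mu_B", "xi_oat"))
  prcc(ua$params[d$set, sampled], d$red_init)
}

#' The nine preset one-way sensitivity analyses
#'
#' Each preset pins one quantity at an alternative point value (or applies a
#' multiplier) across all sampled sets: the bounds of non-IDU drug-use
#' prevalence and PWID prevalence, injecting career length of 5 or 25
#' years, doubling the sampled overdose death rate, and OAT lengthening or
#' shortening the time to permanent cessation by 25% (applied as a distinct
#' cessation rate `xi/(1 +/- 0.25)` for the on-OAT compartments only).
#'
#' @return Named list of preset definitions consumed by
#'   [one_way_analysis()].
#' @export
one_way_presets <- function() {
  list(
    nonIDU_prev_min = list(label = "non-IDU drug use prevalence 8.5%",
                           set = list(target_prev_nonIDU = 0.085)),
    nonIDU_prev_max = list(label = "non-IDU drug use prevalence 9.5%",
                           set = list(target_prev_nonIDU = 0.095)),
    pwid_prev_min = list(label = "PWID prevalence 0.62%",
                         set = list(target_prev_PWID = 0.0062)),
    pwid_prev_max = list(label = "PWID prevalence 1.83%",
                         set = list(target_prev_PWID = 0.0183)),
    duration_min = list(label = "injecting career 5 years",
                        set = list(xi = 1 / 5)),
    duration_max = list(label = "injecting career 25 years",
                        set = list(xi = 1 / 25)),
    overdose_double = list(label = "overdose death rate doubled",
                           multiply = list(mu_OV = 2)),
    oat_slows_cessation = list(label = "OAT lengthens time to cessation 25%",
                               xi_oat_factor = 1 / 1.25),
    oat_speeds_cessation = list(label = "OAT shortens time to cessation 25%",
                                xi_oat_factor = 1 / 0.75)
  )
}

# apply a preset's override to a sampled parameter table (common random
# numbers: the table is sampled once, then columns are modified in place)
apply_preset <- function(params, preset) {
  for (nm in names(preset$set)) {
    params[[nm]] <- preset$set[[nm]]
  }
  for (nm in names(preset$multiply)) {
    params[[nm]] <- params[[nm]] * preset$multiply[[nm]]
  }
  if (!is.null(preset$xi_oat_factor)) {
    params$xi_oat <- params$xi * preset$xi_oat_factor
  } else if ("xi" %in% names(preset$set)) {
    params$xi_oat <- params$xi
  }
  params
}

#' One-way sensitivity analysis against the 60% scale-up scenario
#'
#' Runs the scale-up uncertainty analysis twice over the *same* sampled
#' parameter table (common random numbers): once unmodified and once with
#' the preset's override applied (recalibrating every set). Reports the
#' relative deviation in impact,
#' `100 * (R_override - R_base) / R_base`, where `R` is the mean year-10
#' relative reduction in IDU initiations; positive values mean the override
#' increases the impact of OAT scale-up.
#'
#' @param preset A preset name from [one_way_presets()], or a preset
#'   definition of the same shape.
#' @param n_sets,seed Monte Carlo size and seed (ignored when `base` is
#'   supplied, which fixes both).
#' @param coverage Scale-up coverage analysed (default 0.6).
#' @param years Horizon.
#' @param base Optional precomputed unmodified [uncertainty_analysis()]
#'   sharing the seed, to amortize the base run across presets.
#' @param N0 Population scale.
#' @return List with `preset`, `deviation` (percent), `R_base`,
#'   `R_override`, and the override analysis object.
#' @export
one_way_analysis <- function(preset, n_sets = 1000, seed = 1, coverage = 0.6,
                             years = 10, base = NULL, N0 = 1e6) {
  if (is.character(preset)) {
    presets <- one_way_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset; see names(one_way_presets())")
    }
    preset <- presets[[preset]]
  }
  if (is.null(base)) {
    base <- uncertainty_analysis(n_sets, seed, coverages = coverage,
                                 years = years, N0 = N0)
  }
  stopifnot(inherits(base, "idu_uncertainty"))
  params2 <- apply_preset(base$params, preset)
  ovr <- uncertainty_analysis(coverages = coverage, years = years, N0 = N0,
                              param_table = params2)
  bd <- base$per_set[base$per_set$coverage == coverage, ]
  od <- ovr$per_set[ovr$per_set$coverage == coverage, ]
  R_base <- mean(bd$red_init)
  R_ovr <- mean(od$red_init)
  list(preset = preset$label, deviation = 100 * (R_ovr - R_base) / R_base,
       R_base = R_base, R_override = R_ovr, override = ovr)
}
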