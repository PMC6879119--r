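## Parameter space: sampling distributions for every model parameter and the
## four calibration targets, plus seeded Monte Carlo draws across them.

#' Describe a sampling distribution for one model parameter
#'
#' A `dist_spec` records the distribution family, its parameters, whether the
#' sampled quantity is a duration that must be inverted to a rate
#' (`transform = "reciprocal"`), and the scale on which summaries are
#' reported (`report`).
#'
#' Supported families and their `params`:
#' \describe{
#'   \item{`beta`}{`shape1`, `shape2` (both > 0).}
#'   \item{`uniform`}{`min` < `max`.}
#'   \item{`triangular`}{`min` <= `mode` <= `max`, `min` < `max`.}
#'   \item{`lognormal`}{`median` (> 0) and `sdlog` (> 0); the location is the
#'     log of the median, i.e. the quoted central value is the median, not
#'     the arithmetic mean.}
#'   \item{`three_param_gamma`}{`shape`, `scale` (> 0) and `location`;
#'     draws are `location + Gamma(shape, scale)`.}
#'   \item{`scaled_poisson`}{`lambda` (> 0) and `divisor` (> 0); draws are
#'     `Poisson(lambda) / divisor`.}
#'   \item{`fixed`}{`value`.}
#' }
#'
#' @param family Distribution family name (see Details).
#' @param ... Family-specific parameters.
#' @param transform `"identity"` or `"reciprocal"`. With `"reciprocal"` the
#'   sampled value is a duration in years and the returned draw is its
#'   inverse (a per-year rate).
#' @param report Scale on which [summarize_samples()] reports this
#'   parameter: `"value"` (as stored) or `"duration"` (reciprocal of the
#'   stored rate, harmonic-mean convention for the point summary).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", shape1 = 9.94, shape2 = 36.76)
#' dist_spec("triangular", min = 5, mode = 15, max = 25,
#'           transform = "reciprocal", report = "duration")
#' @export
dist_spec <- function(family, ..., transform = c("identity", "reciprocal"),
                      report = c("value", "duration")) {
  family <- match.arg(family, c(
    "beta", "uniform", "triangular", "lognormal",
    "three_param_gamma", "scaled_poisson", "fixed"
  ))
  transform <- match.arg(transform)
  report <- match.arg(report)
  params <- list(...)
  bad <- function(msg) stop("invalid dist_spec (", family, "): ", msg, call. = FALSE)
  need <- function(nm) {
    if (!all(nm %in% names(params))) {
      bad(paste("requires parameters", paste(nm, collapse = ", ")))
    }
    vals <- unlist(params[nm])
    if (!all(is.finite(vals))) bad("parameters must be finite")
    vals
  }
  switch(family,
    beta = {
      v <- need(c("shape1", "shape2"))
      if (any(v <= 0)) bad("shapes must be > 0")
    },
    uniform = {
      v <- need(c("min", "max"))
      if (v["min"] >= v["max"]) bad("min must be < max")
    },
    triangular = {
      v <- need(c("min", "mode", "max"))
      if (v["min"] > v["mode"] || v["mode"] > v["max"] || v["min"] >= v["max"]) {
        bad("need min <= mode <= max and min < max")
      }
    },
    lognormal = {
      v <- need(c("median", "sdlog"))
      if (v["median"] <= 0 || v["sdlog"] <= 0) bad("median and sdlog must be > 0")
    },
    three_param_gamma = {
      v <- need(c("shape", "scale", "location"))
      if (v["shape"] <= 0 || v["scale"] <= 0) bad("shape and scale must be > 0")
    },
    scaled_poisson = {
      v <- need(c("lambda", "divisor"))
      if (v["lambda"] <= 0 || v["divisor"] <= 0) bad("lambda and divisor must be > 0")
    },
    fixed = {
      need("value")
    }
  )
  structure(list(family = family, params = params, transform = transform,
                 report = report),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec>", x$family, "(",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      ")", if (x$transform == "reciprocal") "[reciprocal]" else "", "\n")
  invisible(x)
}

# inverse-CDF sampler for the triangular distribution
rtriangular <- function(n, min, mode, max) {
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
    min + sqrt(u * (max - min) * (mode - min)),
    max - sqrt((1 - u) * (max - min) * (max - mode))
  )
}

#' Draw from a parameter sampling distribution
#'
#' Draws use the current RNG state; wrap in a seeded context (or use
#' [sample_parameter_sets()]) for reproducibility. With
#' `transform = "reciprocal"` the sampled duration is inverted so the return
#' value is a rate. Non-finite draws (a reciprocal of a zero duration) are
#' resampled up to 100 times before erroring.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @examples
#' set.seed(1)
#' mean(sample_distribution(dist_spec("beta", shape1 = 9.94, shape2 = 36.76), 1e4))
#' @export
sample_distribution <- function(spec, n = 1L) {
  if (!inherits(spec, "dist_spec")) stop("`spec` must be a dist_spec")
  if (n < 0) stop("`n` must be >= 0")
  if (n == 0) return(numeric(0))
  p <- spec$params
  draw <- function(k) {
    switch(spec$family,
      beta = rbeta(k, p$shape1, p$shape2),
      uniform = runif(k, p$min, p$max),
      triangular = rtriangular(k, p$min, p$mode, p$max),
      lognormal = rlnorm(k, meanlog = log(p$median), sdlog = p$sdlog),
      three_param_gamma = p$location + rgamma(k, shape = p$shape, scale = p$scale),
      scaled_poisson = rpois(k, p$lambda) / p$divisor,
      fixed = rep(p$value, k)
    )
  }
  x <- draw(n)
  if (spec$transform == "reciprocal") x <- 1 / x
  for (i in seq_len(100)) {
    bad <- !is.finite(x)
    if (!any(bad)) break
    r <- draw(sum(bad))
    if (spec$transform == "reciprocal") r <- 1 / r
    x[bad] <- r
  }
  if (any(!is.finite(x))) stop("non-finite draws persisted after 100 resampling rounds")
  x
}

#' Default sampling distributions of the model parameter space
#'
#' One `dist_spec` per model parameter and calibration target, reflecting a
#' generic North American setting: roughly 1% PWID prevalence, 9% prevalence
#' of non-injection illicit drug use (excluding cannabis), 21% baseline OAT
#' coverage among PWID, and 17% of initiations self-initiated. Durations
#' (injecting career `1/xi`, OAT episode `1/rho`) are sampled on the
#' duration scale and inverted per draw, so the reported central value is
#' the harmonic mean of durations. Lognormal relative risks are specified by
#' their median.
#'
#' @return Named list of [dist_spec()] objects with names matching the
#'   columns of [sample_parameter_sets()].
#' @export
default_parameter_distributions <- function() {
  list(
    # demographic and drug-use natural history
    mu_B = dist_spec("fixed", value = 69.3, transform = "reciprocal",
                     report = "duration"),
    mu_OV = dist_spec("scaled_poisson", lambda = 62, divisor = 1e4),
    theta = dist_spec("beta", shape1 = 31.46, shape2 = 1239.87),
    xi = dist_spec("triangular", min = 5, mode = 15, max = 25,
                   transform = "reciprocal", report = "duration"),
    rho = dist_spec("uniform", min = 0.25, max = 1.25,
                    transform = "reciprocal", report = "duration"),
    m_inv = dist_spec("three_param_gamma", shape = 0.830, scale = 1,
                      location = 1),
    # relative risks of assisting an initiation
    RR_I = dist_spec("lognormal", median = 4.93, sdlog = 0.19),
    RR_OAT = dist_spec("lognormal", median = 0.55, sdlog = 0.21),
    # relative risks of overdose death around OAT transitions
    RR_OATout = dist_spec("lognormal", median = 2.38, sdlog = 0.23),
    RR_OATin = dist_spec("lognormal", median = 1.97, sdlog = 0.37),
    RR_OATov = dist_spec("lognormal", median = 0.21, sdlog = 0.26),
    # calibration targets
    target_prev_nonIDU = dist_spec("beta", shape1 = 1000, shape2 = 10102),
    target_prev_PWID = dist_spec("beta", shape1 = 13.34, shape2 = 1153.06),
    target_prop_unassisted = dist_spec("beta", shape1 = 18.92, shape2 = 93.33),
    target_oat_coverage = dist_spec("beta", shape1 = 9.94, shape2 = 36.76)
  )
}

#' Sample Monte Carlo parameter sets
#'
#' Draws `n` independent parameter sets, one column per parameter, in a
#' fixed column order under a fixed seed, so overriding a column afterwards
#' (for common-random-number sensitivity analyses) leaves all other columns
#' bitwise identical.
#'
#' @param n Number of parameter sets (>= 1).
#' @param seed Integer seed.
#' @param distributions Named list of [dist_spec()] objects; defaults to
#'   [default_parameter_distributions()]. Entries override the defaults by
#'   name.
#' @return A `data.frame` with `n` rows and one column per parameter,
#'   including an `xi_oat` column (cessation rate while on OAT), equal to
#'   `xi` unless a sensitivity override changes it.
#' @examples
#' p <- sample_parameter_sets(5, seed = 1)
#' p$RR_OAT
#' @export
sample_parameter_sets <- function(n, seed, distributions = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  dists <- default_parameter_distributions()
  if (!is.null(distributions)) {
    stopifnot(is.list(distributions), !is.null(names(distributions)))
    unknown <- setdiff(names(distributions), names(dists))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    dists[names(distributions)] <- distributions
  }
  draws <- with_seed(seed, lapply(dists, sample_distribution, n = n))
  out <- as.data.frame(draws)
  if (any(out$m_inv < 1)) {
    warning("m_inv draws below 1 detected; mean assisted-initiation count must be >= 1")
  }
  if (any(out$mu_OV == 0)) {
    warning(sum(out$mu_OV == 0), " zero overdose-rate draw(s); retained but flagged")
  }
  out$xi_oat <- out$xi
  validate_parameter_sets(out)
  out
}

# minimal invariant checks on a sampled (or overridden) parameter table
validate_parameter_sets <- function(p) {
  num_cols <- c("mu_B", "mu_OV", "theta", "xi", "xi_oat", "rho", "m_inv",
                "RR_I", "RR_OAT", "RR_OATout", "RR_OATin", "RR_OATov",
                "target_prev_nonIDU", "target_prev_PWID",
                "target_prop_unassisted", "target_oat_coverage")
  missing <- setdiff(num_cols, names(p))
  if (length(missing)) stop("parameter table lacks: ", paste(missing, collapse = ", "))
  if (any(!is.finite(as.matrix(p[num_cols])))) stop("non-finite parameter values")
  pos <- c("mu_B", "theta", "xi", "xi_oat", "rho", "RR_I", "RR_OAT", "RR_OATov")
  if (any(as.matrix(p[pos]) <= 0)) stop("rates and relative risks must be > 0")
  if (any(p$mu_OV < 0) || any(p$RR_OATout < 0) || any(p$RR_OATin < 0)) {
    stop("mu_OV, RR_OATout, RR_OATin must be >= 0")
  }
  tgt <- c("target_prev_nonIDU", "target_prev_PWID", "target_prop_unassisted",
           "target_oat_coverage")
  tv <- as.matrix(p[tgt])
  if (any(tv <= 0 | tv >= 1)) stop("calibration targets must lie in (0, 1)")
  invisible(p)
}

#' Summarize sampled parameter sets
#'
#' Per-parameter mean and 2.5--97.5 percentile interval, reported on the
#' scale conventionally quoted for each parameter: duration-valued
#' parameters (`xi`, `rho`, `mu_B`) are summarized as durations, with the
#' point summary being the reciprocal of the mean rate (harmonic-mean
#' convention) and the interval the percentiles of the sampled durations.
#'
#' @param sets Parameter table from [sample_parameter_sets()].
#' @return `data.frame` with columns `parameter`, `mean`, `q2.5`, `q97.5`,
#'   `scale`.
#' @export
summarize_samples <- function(sets) {
  if (!is.data.frame(sets) || nrow(sets) == 0) {
    stop("`sets` must be a non-empty parameter table")
  }
  dists <- default_parameter_distributions()
  rows <- lapply(names(dists), function(nm) {
    x <- sets[[nm]]
    if (is.null(x)) return(NULL)
    sc <- dists[[nm]]$report
    if (sc == "duration") {
      d <- 1 / x
      data.frame(parameter = nm, mean = 1 / mean(x),
                 q2.5 = unname(quantile(d, 0.025)),
                 q97.5 = unname(quantile(d, 0.975)), scale = "duration")
    } else {
      data.frame(parameter = nm, mean = mean(x),
                 q2.5 = unname(quantile(x, 0.025)),
                 q97.5 = unname(quantile(x, 0.975)), scale = "value")
    }
  })
  do.call(rbind, rows)
}
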