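## Effect-size statistics: modified Poisson regression (log link on a
## binary outcome with robust sandwich variance) and REML random-effects
## pooling of site-level log relative risks.

#' Modified Poisson regression with robust variance
#'
#' Fits a Poisson-family log-link GLM to a binary outcome and replaces the
#' model-based variance with the robust (HC0 sandwich) estimator, yielding
#' covariate-adjusted relative risks with valid standard errors despite the
#' binomial outcome. Confidence intervals use the normal approximation,
#' `exp(log_rr +/- z * se)`.
#'
#' @param data Data frame of individual records.
#' @param outcome Name of the binary outcome column (0/1 or logical).
#' @param exposures Character vector of exposure terms whose RRs are
#'   reported.
#' @param covariates Character vector of adjustment terms (may be empty).
#' @param level Confidence level (default 0.95).
#' @return `data.frame` of class `idu_effects` with one row per estimated
#'   coefficient of each exposure: `term`, `log_rr`, `se`, `rr`, `ci_lower`,
#'   `ci_upper`.
#' @examples
#' d <- data.frame(y = rep(c(1, 0, 1, 0), c(20, 180, 10, 190)),
#'                 x = rep(c(1, 0), c(200, 200)))
#' fit_modified_poisson(d, "y", "x")  # RR = 2 exactly
#' @export
fit_modified_poisson <- function(data, outcome, exposures,
                                 covariates = character(), level = 0.95) {
  stopifnot(is.data.frame(data), length(exposures) >= 1)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (sum(y) == 0) stop("no outcome events; relative risks undefined")
  terms <- c(exposures, covariates)
  miss <- setdiff(terms, names(data))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  cc <- complete.cases(data[terms]) & !is.na(y)
  if (!all(cc)) stop("missing values in modelled variables; subset first")
  f <- as.formula(paste("y_ ~", paste(terms, collapse = " + ")))
  d2 <- data[terms]
  d2$y_ <- y
  fit <- glm(f, family = poisson(link = "log"), data = d2)
  X <- model.matrix(fit)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  mu <- fit$fitted.values
  # HC0 sandwich: bread = (X' diag(mu) X)^-1, meat = X' diag((y-mu)^2) X
  bread <- solve(crossprod(X, X * mu))
  meat <- crossprod(X, X * (y - mu)^2)
  V <- bread %*% meat %*% bread
  se_all <- sqrt(diag(V))
  b <- coef(fit)
  z <- qnorm(1 - (1 - level) / 2)
  keep <- unlist(lapply(exposures, function(e) {
    grep(paste0("^", e), names(b), value = TRUE)
  }))
  keep <- setdiff(unique(keep), "(Intercept)")
  out <- data.frame(
    term = keep,
    log_rr = unname(b[keep]),
    se = unname(se_all[keep]),
    row.names = NULL
  )
  out$rr <- exp(out$log_rr)
  out$ci_lower <- exp(out$log_rr - z * out$se)
  out$ci_upper <- exp(out$log_rr + z * out$se)
  class(out) <- c("idu_effects", "data.frame")
  out
}

#' Log-scale standard error from a published confidence interval
#'
#' Back-calculates the standard error of a log relative risk from the
#' published point estimate and CI: `se = (log(upper) - log(lower)) / (2 z)`.
#'
#' @param point,lower,upper Published RR and CI bounds
#'   (`0 < lower <= point <= upper`).
#' @param level Confidence level of the published interval.
#' @return Standard error on the log-RR scale (0 flagged with a warning when
#'   the interval is degenerate).
#' @examples
#' se_from_ci(5.70, 3.60, 9.02) # ~0.234
#' @export
se_from_ci <- function(point, lower, upper, level = 0.95) {
  if (any(lower <= 0) || any(lower > point) || any(point > upper)) {
    stop("need 0 < lower <= point <= upper")
  }
  z <- qnorm(1 - (1 - level) / 2)
  se <- (log(upper) - log(lower)) / (2 * z)
  if (any(se == 0)) warning("degenerate interval: se = 0")
  se
}

#' REML random-effects pooling of log relative risks
#'
#' Estimates the between-study variance `tau^2` by restricted maximum
#' likelihood (bounded one-dimensional optimization on `[0, 10]`), then
#' pools with inverse-variance weights `1 / (se_i^2 + tau^2)`.
#'
#' @param log_rr Study log relative risks.
#' @param se Their standard errors (> 0).
#' @param labels Optional study labels.
#' @param level Confidence level for the pooled interval.
#' @return Object of class `idu_pooled`: list with `log_rr`, `se`, `rr`,
#'   `ci_lower`, `ci_upper`, `tau2`, and a `studies` data frame with
#'   normalized weights.
#' @examples
#' pool_random_effects(log(c(5.70, 2.73, 4.79)),
#'                     se_from_ci(c(5.70, 2.73, 4.79),
#'                                c(3.60, 1.04, 2.14),
#'                                c(9.02, 7.17, 10.72)))
#' @export
pool_random_effects <- function(log_rr, se, labels = NULL, level = 0.95) {
  k <- length(log_rr)
  stopifnot(k >= 1, length(se) == k)
  if (any(se <= 0)) stop("all standard errors must be > 0")
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  v <- se^2
  if (k == 1) {
    tau2 <- 0
    message("single estimate: returned unchanged with tau2 = 0")
  } else {
    restricted_ll <- function(t2) {
      w <- 1 / (v + t2)
      mu <- sum(w * log_rr) / sum(w)
      -0.5 * sum(log(v + t2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (log_rr - mu)^2)
    }
    opt <- optimize(restricted_ll, c(0, 10), maximum = TRUE, tol = 1e-12)
    tau2 <- if (restricted_ll(0) >= opt$objective) 0 else opt$maximum
  }
  w <- 1 / (v + tau2)
  mu <- sum(w * log_rr) / sum(w)
  se_p <- sqrt(1 / sum(w))
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    log_rr = mu, se = se_p, rr = exp(mu),
    ci_lower = exp(mu - z * se_p), ci_upper = exp(mu + z * se_p),
    tau2 = tau2,
    studies = data.frame(study = labels, log_rr = log_rr, se = se,
                         rr = exp(log_rr), weight = w / sum(w))
  ), class = "idu_pooled")
}

#' @export
print.idu_pooled <- function(x, ...) {
  cat(sprintf("<idu_pooled> RR %.3f (%.0f%% CI %.3f-%.3f), tau^2 = %.4g, k = %d\n",
              x$rr, 95, x$ci_lower, x$ci_upper, x$tau2, nrow(x$studies)))
  invisible(x)
}

#' Published site-level adjusted relative risks
#'
#' The covariate-adjusted site-specific RRs (with 95% CIs) for the two
#' exposures of interest, as published from the three-city PWID cohorts.
#' The individual-level data behind them are not deposited, so these serve
#' as the inputs to [pool_random_effects()]; OAT enrollment could not be
#' modelled in Tijuana (2.1% enrollment).
#'
#' @return `data.frame` with columns `exposure`, `site`, `rr`, `ci_lower`,
#'   `ci_upper`.
#' @export
primer_site_estimates <- function() {
  data.frame(
    exposure = c(rep("history_prior", 3), rep("oat_recent", 2)),
    site = c("Vancouver", "SanDiego", "Tijuana", "Vancouver", "SanDiego"),
    rr = c(5.70, 2.73, 4.79, 0.58, 0.26),
    ci_lower = c(3.60, 1.04, 2.14, 0.37, 0.04),
    ci_upper = c(9.02, 7.17, 10.72, 0.88, 1.79)
  )
}

#' Pool the published site estimates for one exposure
#'
#' @param exposure `"history_prior"` or `"oat_recent"`.
#' @return An `idu_pooled` object (see [pool_random_effects()]).
#' @export
pool_primer_estimates <- function(exposure = c("history_prior", "oat_recent")) {
  exposure <- match.arg(exposure)
  d <- primer_site_estimates()
  d <- d[d$exposure == exposure, ]
  pool_random_effects(log(d$rr), se_from_ci(d$rr, d$ci_lower, d$ci_upper),
                      labels = d$site)
}
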