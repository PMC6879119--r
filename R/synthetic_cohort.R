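## Synthetic multi-site cohort generator: individual-level records with the
## published marginal structure of the three PWID cohorts and user-specified
## true relative risks, so the regression and pooling machinery can be
## validated by parameter recovery without any (non-deposited) study data.

#' Default site specifications for the synthetic cohort
#'
#' Three site specifications reproducing the published marginals: sample
#' sizes 1,737 / 346 / 532 (Vancouver / San Diego / Tijuana), recent-OAT and
#' assisting-history prevalences, covariate marginals (age, gender, unstable
#' housing, injection frequency, methamphetamine injection, speedball
#' injection in Vancouver only), and outcome prevalences 4.5% / 5.2% / 4.3%
#' for recently assisting an IDU initiation. Default true RRs are the pooled
#' values (history 4.93, OAT 0.55); covariate effects are modest non-null
#' placeholders, not estimates. Vancouver's three-cohort membership split is
#' synthetic (not published).
#'
#' @param rr_history,rr_oat True relative risks for the two exposures.
#' @return Named list of `site_spec` lists.
#' @export
default_primer_spec <- function(rr_history = 4.93, rr_oat = 0.55) {
  rr_common <- list(
    history_prior = rr_history, oat_recent = rr_oat,
    age10 = 0.95,       # per decade of age
    gender_male = 1.1,
    unstable_housing = 1.2,
    inj_lt_daily = 1.3, inj_daily = 1.6, # vs no recent injection
    meth_inject = 1.2, speedball_inject = 1.2,
    cohortARYS = 1.0, cohortVIDUS = 1.0
  )
  spec <- function(site, n, oat, hist, prev, age_mean, age_sd, female,
                   housing, inj_freq, meth, speedball = NULL,
                   cohorts = NULL) {
    structure(list(
      site = site, n = n, oat_recent = oat, history_prior = hist,
      outcome_prev = prev, age_mean = age_mean, age_sd = age_sd,
      female = female, unstable_housing = housing,
      inj_freq = inj_freq / sum(inj_freq), meth_inject = meth,
      speedball_inject = speedball, cohorts = cohorts, rr = rr_common
    ), class = "site_spec")
  }
  list(
    Vancouver = spec("Vancouver", 1737, oat = 0.494, hist = 0.227,
                     prev = 0.045, age_mean = 42.98, age_sd = 12.57,
                     female = 0.377, housing = 0.251,
                     inj_freq = c(none = 0.340, lt_daily = 0.310, daily = 0.351),
                     meth = 0.346, speedball = 0.068,
                     cohorts = c(ACCESS = 0.30, ARYS = 0.25, VIDUS = 0.45)),
    SanDiego = spec("SanDiego", 346, oat = 0.197, hist = 0.353,
                    prev = 0.052, age_mean = 46.82, age_sd = 11.29,
                    female = 0.283, housing = 0.399,
                    inj_freq = c(none = 0.301, lt_daily = 0.376, daily = 0.324),
                    meth = 0.457),
    Tijuana = spec("Tijuana", 532, oat = 0.021, hist = 0.118,
                   prev = 0.043, age_mean = 41.05, age_sd = 8.68,
                   female = 0.385, housing = 0.152,
                   inj_freq = c(none = 0.173, lt_daily = 0.070, daily = 0.758),
                   meth = 0.117)
  )
}

# risk multiplier implied by a participant's exposures/covariates under the
# multiplicative (log-link) outcome model
risk_multiplier <- function(d, rr) {
  mult <- rr$history_prior^d$history_prior *
    rr$oat_recent^d$oat_recent *
    rr$age10^((d$age - mean(d$age)) / 10) *
    rr$gender_male^(d$gender == "male") *
    rr$unstable_housing^d$unstable_housing *
    rr$inj_lt_daily^(d$inj_freq == "lt_daily") *
    rr$inj_daily^(d$inj_freq == "daily") *
    rr$meth_inject^d$meth_inject
  if (!is.null(d$speedball_inject)) {
    mult <- mult * rr$speedball_inject^d$speedball_inject
  }
  if (!is.null(d$cohort)) {
    mult <- mult * rr$cohortARYS^(d$cohort == "ARYS") *
      rr$cohortVIDUS^(d$cohort == "VIDUS")
  }
  mult
}

#' Generate a synthetic site cohort
#'
#' Covariates are drawn independently from the site's marginals (the
#' published tables report marginals only, so no correlation structure is
#' invented). The binary outcome is Bernoulli with risk
#' `baseline_risk * prod(RR^exposure)`, where `baseline_risk` is solved
#' numerically so the marginal outcome prevalence matches the spec.
#' Individual risks above 1 are truncated; generation fails if more than 1%
#' of records would be truncated.
#'
#' @param spec A `site_spec` from [default_primer_spec()].
#' @param seed Integer seed.
#' @param n Optional overriding sample size (e.g. for parameter-recovery
#'   tests at large n).
#' @return `data.frame` with one row per participant: `site`, `recent_assist`
#'   (outcome), `oat_recent`, `history_prior`, `age`, `gender`,
#'   `unstable_housing`, `inj_freq`, `meth_inject`, plus `speedball_inject`
#'   and `cohort` where the site collects them. Attribute `truncated` gives
#'   the truncation fraction.
#' @examples
#' v <- generate_cohort(default_primer_spec()$Vancouver, seed = 1)
#' mean(v$oat_recent)
#' @export
generate_cohort <- function(spec, seed, n = NULL) {
  stopifnot(inherits(spec, "site_spec"))
  if (is.null(n)) n <- spec$n
  if (n == 0) {
    d <- data.frame(site = character(), recent_assist = integer(),
                    oat_recent = integer(), history_prior = integer(),
                    age = numeric(), gender = character(),
                    unstable_housing = integer(), inj_freq = character(),
                    meth_inject = integer())
    attr(d, "truncated") <- 0
    return(d)
  }
  with_seed(seed, {
    d <- data.frame(
      site = spec$site,
      oat_recent = rbinom(n, 1, spec$oat_recent),
      history_prior = rbinom(n, 1, spec$history_prior),
      age = rnorm(n, spec$age_mean, spec$age_sd),
      gender = ifelse(runif(n) < spec$female, "female", "male"),
      unstable_housing = rbinom(n, 1, spec$unstable_housing),
      inj_freq = sample(names(spec$inj_freq), n, replace = TRUE,
                        prob = spec$inj_freq),
      meth_inject = rbinom(n, 1, spec$meth_inject)
    )
    d$inj_freq <- factor(d$inj_freq, levels = names(spec$inj_freq))
    if (!is.null(spec$speedball_inject)) {
      d$speedball_inject <- rbinom(n, 1, spec$speedball_inject)
    }
    if (!is.null(spec$cohorts)) {
      d$cohort <- factor(sample(names(spec$cohorts), n, replace = TRUE,
                                prob = spec$cohorts),
                         levels = sort(names(spec$cohorts)))
    }
    mult <- risk_multiplier(d, spec$rr)
    # solve baseline risk so that E[min(b * mult, 1)] = target prevalence
    f <- function(b) mean(pmin(b * mult, 1)) - spec$outcome_prev
    if (f(1 / max(mult)) > 0) {
      b <- uniroot(f, c(1e-12, 1 / max(mult)), tol = 1e-12)$root
    } else {
      b <- uniroot(f, c(1 / max(mult), 1), tol = 1e-12)$root
    }
    risk <- pmin(b * mult, 1)
    trunc_frac <- mean(b * mult > 1)
    if (trunc_frac >= 0.01) {
      stop("risk truncation rate ", round(100 * trunc_frac, 2),
           "% exceeds 1%; reduce effect sizes or prevalence")
    }
    d$recent_assist <- rbinom(n, 1, risk)
    attr(d, "truncated") <- trunc_frac
    d
  })
}

#' Default regression formula terms for a site
#'
#' Encodes the site-specific variable-availability rules: no OAT term for
#' Tijuana (2.1% enrollment), speedball and cohort membership only for
#' Vancouver.
#'
#' @param site Site name.
#' @return List with `exposures` and `covariates` character vectors.
#' @export
default_site_terms <- function(site) {
  base_cov <- c("age", "gender", "unstable_housing", "inj_freq", "meth_inject")
  switch(site,
    Vancouver = list(exposures = c("history_prior", "oat_recent"),
                     covariates = c(base_cov, "speedball_inject", "cohort")),
    SanDiego = list(exposures = c("history_prior", "oat_recent"),
                    covariates = base_cov),
    Tijuana = list(exposures = "history_prior", covariates = base_cov),
    stop("unknown site: ", site)
  )
}
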