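#' Configuration for the synthetic cohort generator
#'
#' Defines the data-generating process the package's tests and simulations
#' run on: covariate marginals matching the pooled descriptive statistics of
#' a localized prostate cancer cohort, confounded treatment assignment
#' (radiotherapy patients older, sicker, with worse tumors), three
#' Weibull/piecewise transition processes sharing the likelihood's hazard
#' code, administrative censoring at 15 years plus independent uniform loss
#' to follow-up, and per-field missingness at the published rates.
#'
#' Default true treatment log-hazard-ratios are log(0.80) for the
#' treatment-to-CF transition, log(1.45) for death from other causes and
#' log(1.95) for death after CF, so that recovery simulations target
#' effects of realistic magnitude.
#'
#' @param n cohort size (default 4544).
#' @param seed integer seed stored in the config and used by
#'   [generate_cohort()].
#' @param truth optional list of three [transition_params()] (`t12`, `t13`,
#'   `t23`) overriding the default truth.
#' @param treatment_model named coefficient vector for the logistic
#'   assignment model (linear predictor on covariates); its intercept is
#'   calibrated at generation time so the radiotherapy fraction matches
#'   `rt_fraction`.
#' @param rt_fraction target marginal probability of radiotherapy
#'   (default 775/4544).
#' @param censoring list `admin` (administrative cap, years) and `ltfu_max`
#'   (upper bound of the uniform loss-to-follow-up time).
#' @param missingness named list per maskable field: either
#'   `list(mechanism = "mcar", rate = r)` or `list(mechanism =
#'   "mar_treatment", rate = c(surgery = r1, radiotherapy = r2))`.  MAR
#'   mechanisms may depend only on the always-observed fields.
#' @param copula_rho correlation between the log-PSA and Gleason latent
#'   scores (Gaussian copula); 0 = independent (default).
#' @param spec the [idm_spec()] (with explicit centering constants) under
#'   which the truth's `beta` vectors are defined.
#' @return object of class `idm_synth_config`.
#' @export
synthetic_config <- function(n = 4544, seed = 1, truth = NULL,
                             treatment_model = NULL,
                             rt_fraction = 775 / 4544,
                             censoring = list(admin = 15, ltfu_max = 17),
                             missingness = default_missingness(),
                             copula_rho = 0,
                             spec = NULL) {
  stopifnot(n >= 1, rt_fraction > 0, rt_fraction < 1,
            censoring$admin > 0, censoring$ltfu_max > 0,
            abs(copula_rho) < 1)
  if (is.null(spec)) {
    spec <- idm_spec(centering = list(age_center = 61.2,
                                      log_psa = c(2.0, 0.75),
                                      log_volume = c(log(40), 0.40)))
  }
  if (is.null(truth)) truth <- default_truth(spec)
  for (tp in truth) {
    h <- .base_cumhaz(tp, censoring$admin)
    if (!is.finite(h)) stop("truth parameters give non-finite hazard on (0, 15]")
  }
  if (is.null(treatment_model)) {
    treatment_model <- c(age10 = 0.95, cci_1 = 0.9, cci_2 = 0.6, cci_3plus = 1.3,
                         gleason_7_43 = 0.45, gleason_8 = 0.85, gleason_9_10 = 1.1,
                         ct_2 = 0.35, ct_3 = 2.2, race_aa = 0.8,
                         txyear_2001_2006 = 0.55, txyear_2007_2013 = -0.45)
  }
  .validate_missingness(missingness)
  structure(list(n = as.integer(n), seed = as.integer(seed), truth = truth,
                 treatment_model = treatment_model, rt_fraction = rt_fraction,
                 censoring = censoring, missingness = missingness,
                 copula_rho = copula_rho, spec = spec,
                 marginals = .default_marginals()),
            class = "idm_synth_config")
}

# pooled observed frequencies of the emulated cohort's descriptive table
.default_marginals <- function() {
  list(
    age = c(mean = 61.2, sd = 8.0),
    log_volume = c(mean = log(40), sd = 0.40),
    log_psa = c(mean = 2.0, sd = 0.75),
    cci = c("0" = 2599, "1" = 527, "2" = 354, "3+" = 136) / 3616,
    gleason = c("5/6" = 2038, "7=3+4" = 1513, "7=4+3" = 521,
                "8" = 245, "9/10" = 205) / 4522,
    pni = 1108 / 4450,
    ct = c("1" = 3117, "2" = 1354, "3" = 60) / 4531,
    race = c(White = 3358, AfricanAmerican = 245, Other = 36) / 3639,
    tx_year = c("1996-2000" = 1205, "2001-2006" = 1578, "2007-2013" = 1761) / 4544
  )
}

#' Default missingness mechanisms (published per-arm rates)
#' @return named list suitable for [synthetic_config()]'s `missingness`.
#' @export
default_missingness <- function() {
  list(
    gland_volume = list(mechanism = "mcar", rate = 0.346),
    psa = list(mechanism = "mcar", rate = 0.001),
    cci = list(mechanism = "mar_treatment",
               rate = c(surgery = 0.244, radiotherapy = 0.015)),
    gleason = list(mechanism = "mar_treatment",
                   rate = c(surgery = 0.001, radiotherapy = 0.026)),
    pni = list(mechanism = "mar_treatment",
               rate = c(surgery = 0.008, radiotherapy = 0.083)),
    ct = list(mechanism = "mcar", rate = 0.003),
    race = list(mechanism = "mar_treatment",
                rate = c(surgery = 0.235, radiotherapy = 0.026))
  )
}

.maskable_fields <- c("gland_volume", "psa", "cci", "gleason", "pni", "ct", "race")

.validate_missingness <- function(m) {
  bad <- setdiff(names(m), .maskable_fields)
  if (length(bad))
    stop("missingness configured for unmaskable field(s): ",
         paste(bad, collapse = ", "),
         " (MAR predictors age/treatment/tx_year are never maskable)")
  for (f in names(m)) {
    mech <- m[[f]]$mechanism
    if (!mech %in% c("mcar", "mar_treatment"))
      stop("unknown missingness mechanism: ", mech)
    r <- m[[f]]$rate
    if (any(r < 0 | r > 1)) stop("missingness rates must be in [0, 1]")
  }
  invisible(m)
}

#' Default true transition parameters
#'
#' Weibull baselines calibrated so that a cohort of 4544 with ~8.5-year
#' median follow-up yields event counts on the scale of the emulated study
#' (about 3.5% CF, 8.3% death from other causes, and death after CF in a
#' bit over half of CF cases), with covariate log-HRs of realistic size and
#' treatment effects log(0.80), log(1.45), log(1.95).
#'
#' @param spec the [idm_spec()] whose design columns the `beta` vectors
#'   must match.
#' @return list of three [transition_params()].
#' @export
default_truth <- function(spec = NULL) {
  if (is.null(spec)) spec <- idm_spec()
  if (is.null(spec$centering$age_center)) {
    spec$centering <- list(age_center = 61.2, log_psa = c(2.0, 0.75),
                           log_volume = c(log(40), 0.40))
  }
  z12 <- c(treatment_rt = log(0.80), age10 = 0.05, log_psa_std = 0.45,
           log_volume_std = -0.05, cci_1 = 0.05, cci_2 = 0.05, cci_3plus = 0.10,
           gleason_7_34 = 0.45, gleason_7_43 = 0.85, gleason_8 = 1.25,
           gleason_9_10 = 1.70, pni = 0.50, ct_2 = 0.35, ct_3 = 0.90,
           race_aa = 0.05, race_other = 0.00,
           txyear_2001_2006 = -0.35, txyear_2007_2013 = -0.75)
  z13 <- c(treatment_rt = log(1.45), age10 = 0.60, log_psa_std = 0.05,
           log_volume_std = 0.00, cci_1 = 0.30, cci_2 = 0.55, cci_3plus = 0.95,
           gleason_7_34 = 0.05, gleason_7_43 = 0.10, gleason_8 = 0.10,
           gleason_9_10 = 0.15, pni = 0.05, ct_2 = 0.05, ct_3 = 0.10,
           race_aa = 0.10, race_other = 0.00,
           txyear_2001_2006 = -0.05, txyear_2007_2013 = -0.10)
  z23 <- c(treatment_rt = log(1.95), age10 = 0.40, log_psa_std = 0.10,
           gleason_8 = 0.20, gleason_9_10 = 0.60, cftime15 = -0.40)
  keep <- function(z, tr) {
    # align to the columns the spec produces; unnamed (incl. interaction)
    # columns get a true effect of zero
    cols <- colnames(design_matrix(.reference_record(), spec, tr))
    out <- z[cols]
    out[is.na(out)] <- 0
    names(out) <- cols
    out
  }
  list(t12 = transition_params("weibull", shape = 1.20, scale = 210,
                               beta = keep(z12, "t12")),
       t13 = transition_params("weibull", shape = 1.50, scale = 56,
                               beta = keep(z13, "t13")),
       t23 = transition_params("weibull", shape = 1.00, scale = 5.5,
                               beta = keep(z23, "t23")))
}

# a complete reference-level record (used to enumerate design columns)
.reference_record <- function() {
  data.frame(id = "ref", age = 61.2, gland_volume = 40, psa = exp(2),
             cci = "0", gleason = "5/6", pni = 0, ct = "1", race = "White",
             tx_year = "1996-2000", treatment = "surgery",
             cf_time = 0, cf_event = 0, death_time = 0, death_event = 0,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Simulates covariates from the configured marginals, assigns treatment
#' from the confounded logistic model (intercept calibrated so the marginal
#' radiotherapy fraction matches the target), then simulates the
#' three-transition semi-Markov event history by inversion of the cumulative
#' hazards -- the same hazard code the likelihood uses.  Latent times T12 and
#' T13 are drawn from the 1->2 and 1->3 transitions given the covariates; if
#' T12 comes first and precedes censoring the patient enters CF at u = T12
#' and a 2->3 time is drawn on the reset clock with u/15 in the linear
#' predictor.  Observed times and indicators follow by censoring at
#' min(administrative cap, loss to follow-up); events exactly at the cap
#' count as events.
#'
#' @param config an [synthetic_config()].
#' @return list with `cohort` (complete, pre-missingness records), `truth`
#'   (the generating [transition_params()]), `spec`, and
#'   `treatment_intercept` (the calibrated logistic intercept).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "idm_synth_config"))
  set.seed(config$seed)
  n <- config$n
  mg <- config$marginals
  rcat <- function(p) names(p)[1L + findInterval(stats::runif(n), cumsum(p),
                                                 rightmost.closed = TRUE)]
  age <- stats::rnorm(n, mg$age["mean"], mg$age["sd"])
  age <- pmin(pmax(age, 40), 84)
  zpsa <- stats::rnorm(n)
  log_psa <- mg$log_psa["mean"] + mg$log_psa["sd"] * zpsa
  log_vol <- stats::rnorm(n, mg$log_volume["mean"], mg$log_volume["sd"])
  if (config$copula_rho != 0) {
    # Gaussian copula: Gleason category from a latent score correlated with
    # the log-PSA score; thresholds at the marginal cumulative frequencies
    zg <- config$copula_rho * zpsa +
      sqrt(1 - config$copula_rho^2) * stats::rnorm(n)
    br <- stats::qnorm(cumsum(mg$gleason))
    gleason <- names(mg$gleason)[1L + findInterval(zg, br[-length(br)])]
  } else {
    gleason <- rcat(mg$gleason)
  }
  df <- data.frame(
    id = sprintf("S%05d", seq_len(n)), age = age,
    gland_volume = exp(log_vol), psa = exp(log_psa),
    cci = rcat(mg$cci), gleason = gleason,
    pni = as.numeric(stats::runif(n) < mg$pni),
    ct = rcat(mg$ct), race = rcat(mg$race), tx_year = rcat(mg$tx_year),
    treatment = "surgery", cf_time = 0, cf_event = 0,
    death_time = 0, death_event = 0, stringsAsFactors = FALSE)

  # confounded treatment assignment, intercept calibrated to the target mix
  Xt <- design_matrix(df, config$spec, "t12")
  tm <- config$treatment_model
  miss_tm <- setdiff(names(tm), colnames(Xt))
  if (length(miss_tm)) stop("treatment_model names not in design: ",
                            paste(miss_tm, collapse = ", "))
  eta <- drop(Xt[, names(tm), drop = FALSE] %*% tm)
  a <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - config$rt_fraction,
                      interval = c(-30, 30))$root
  df$treatment <- ifelse(stats::runif(n) < stats::plogis(a + eta),
                         "radiotherapy", "surgery")

  # latent transition times by cumulative-hazard inversion
  truth <- config$truth
  draw_time <- function(tp, X) {
    lp <- drop(X %*% tp$beta)
    E <- stats::rexp(length(lp))
    t <- .base_cumhaz_inv(tp, E * exp(-lp))
    bad <- is.nan(t) | t < 0  # +Inf is a legitimate "never" draw
    tries <- 0
    while (any(bad) && tries < 50) {
      t[bad] <- .base_cumhaz_inv(tp, stats::rexp(sum(bad)) * exp(-lp[bad]))
      bad <- is.nan(t) | t < 0
      tries <- tries + 1
    }
    if (any(bad)) warning(sum(bad), " non-invertible survival draws resampled to cap")
    t[bad] <- Inf
    t
  }
  T12 <- draw_time(truth$t12, design_matrix(df, config$spec, "t12"))
  T13 <- draw_time(truth$t13, design_matrix(df, config$spec, "t13"))
  C <- pmin(config$censoring$admin,
            stats::runif(n, 0, config$censoring$ltfu_max))

  cf <- T12 <= pmin(T13, C)
  df$cf_event <- as.numeric(cf)
  df$cf_time <- ifelse(cf, T12, pmin(T13, C))
  # death without CF
  d13 <- !cf & T13 <= C
  df$death_event <- as.numeric(d13)
  df$death_time <- pmin(T13, C)
  # post-CF sojourn on the reset clock
  if (any(cf)) {
    sub <- df[cf, , drop = FALSE]
    sub$cf_time <- T12[cf]
    X23 <- design_matrix(sub, config$spec, "t23")
    V <- draw_time(truth$t23, X23)
    dead23 <- T12[cf] + V <= C[cf]
    df$death_event[cf] <- as.numeric(dead23)
    df$death_time[cf] <- pmin(T12[cf] + V, C[cf])
  }
  df$cf_time <- pmin(df$cf_time, df$death_time)
  cohort <- validate_cohort(df)
  list(cohort = cohort, truth = truth, spec = config$spec,
       treatment_intercept = a)
}

#' Mask covariates according to the configured missingness
#'
#' Each maskable field is masked independently per its mechanism: MCAR at a
#' single rate, or MAR with a rate depending on the (always observed)
#' treatment arm.  The pre-masking values are retained in the
#' `"complete_values"` attribute for recovery tests.
#'
#' @param cohort complete cohort (from [generate_cohort()]).
#' @param config an [synthetic_config()] (its `missingness` and `seed` + 1
#'   are used), or a missingness list.
#' @return cohort with `NA`s introduced.
#' @export
apply_missingness <- function(cohort, config) {
  m <- if (inherits(config, "idm_synth_config")) {
    set.seed(config$seed + 1L)
    config$missingness
  } else config
  .validate_missingness(m)
  complete <- cohort[, names(m), drop = FALSE]
  n <- nrow(cohort)
  for (f in names(m)) {
    mech <- m[[f]]$mechanism
    r <- m[[f]]$rate
    p <- if (mech == "mcar") rep(r, n) else
      unname(r[as.character(cohort$treatment)])
    mask <- stats::runif(n) < p
    cohort[[f]][mask] <- NA
  }
  attr(cohort, "complete_values") <- complete
  cohort
}
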