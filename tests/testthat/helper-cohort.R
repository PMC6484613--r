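# shared fixtures, built in code

# spec with the synthetic generator's fixed centering constants
synth_spec <- function(...) {
  idm_spec(centering = list(age_center = 61.2, log_psa = c(2.0, 0.75),
                            log_volume = c(log(40), 0.40)), ...)
}

# a tiny fully-observed cohort with one subject per outcome pattern
toy_cohort <- function() {
  validate_cohort(data.frame(
    id = c("a", "b", "c"),
    age = c(61.2, 71.2, 55),
    gland_volume = c(40, 35, 50),
    psa = c(exp(2), 10, 5),
    cci = c("0", "1", "3+"),
    gleason = c("5/6", "7=4+3", "9/10"),
    pni = c(0, 0, 1),
    ct = c("1", "2", "3"),
    race = c("White", "AfricanAmerican", "Other"),
    tx_year = c("1996-2000", "2001-2006", "2007-2013"),
    treatment = c("surgery", "radiotherapy", "surgery"),
    cf_time = c(10, 6, 4),     # a: censored at 10; b: dead (other) at 6
    cf_event = c(0, 0, 1),     # c: CF at 4, dead at 9
    death_time = c(10, 6, 9),
    death_event = c(0, 1, 1),
    stringsAsFactors = FALSE))
}

# moderately sized synthetic cohort for fitting tests (complete data)
small_synth <- function(n = 600, seed = 99, ...) {
  generate_cohort(synthetic_config(n = n, seed = seed, ...))
}

# no-covariate exponential spec for the conjugate sampler checks
conj_spec <- function() {
  idm_spec(terms = list(t12 = character(0), t13 = character(0),
                        t23 = character(0)),
           baseline = list(t12 = "exponential", t13 = "exponential",
                           t23 = "exponential"),
           centering = list(age_center = 61.2, log_psa = c(2, 0.75),
                            log_volume = c(log(40), 0.4)))
}

# simple no-covariate transition parameter sets
null_spec <- function() {
  idm_spec(terms = list(t12 = "treatment", t13 = "treatment",
                        t23 = c("treatment", "cf_time")),
           centering = list(age_center = 61.2, log_psa = c(2.0, 0.75),
                            log_volume = c(log(40), 0.40)))
}
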