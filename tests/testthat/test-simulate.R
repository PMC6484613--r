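# truth with zero covariate effects and chosen baselines, aligned to a spec
zero_beta_truth <- function(sp, fams, pars) {
  ref <- bayesidm:::.reference_record()
  out <- list()
  for (tr in c("t12", "t13", "t23")) {
    cols <- colnames(design_matrix(ref, sp, tr))
    beta <- stats::setNames(rep(0, length(cols)), cols)
    out[[tr]] <- do.call(transition_params,
                         c(list(family = fams[[tr]], beta = beta), pars[[tr]]))
  }
  out
}

test_that("generation is bit-reproducible given the seed", {
  cfg <- synthetic_config(n = 300, seed = 123)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  m1 <- apply_missingness(g1$cohort, cfg)
  m2 <- apply_missingness(g2$cohort, cfg)
  expect_identical(m1, m2)
})

test_that("15-year CF incidence matches the competing-risks closed form", {
  sp <- synth_spec()
  l12 <- 0.004; l13 <- 0.020
  truth <- zero_beta_truth(
    sp, list(t12 = "exponential", t13 = "exponential", t23 = "exponential"),
    list(t12 = list(scale = 1 / l12), t13 = list(scale = 1 / l13),
         t23 = list(scale = 5)))
  cfg <- synthetic_config(n = 20000, seed = 77, truth = truth, spec = sp,
                          censoring = list(admin = 15, ltfu_max = 1e9))
  g <- generate_cohort(cfg)
  p_cf <- l12 / (l12 + l13) * (1 - exp(-(l12 + l13) * 15))
  se <- sqrt(p_cf * (1 - p_cf) / 20000)
  expect_lt(abs(mean(g$cohort$cf_event) - p_cf), 3 * se)
  # the radiotherapy fraction is calibrated to the emulated cohort's mix
  expect_lt(abs(mean(g$cohort$treatment == "radiotherapy") - 775 / 4544),
            3 * sqrt(0.17 * 0.83 / 20000))
  # confounding direction: radiotherapy patients are older
  expect_gt(mean(g$cohort$age[g$cohort$treatment == "radiotherapy"]),
            mean(g$cohort$age[g$cohort$treatment == "surgery"]) + 2)
})

test_that("a null 1->2 transition produces no CF events", {
  sp <- synth_spec()
  truth <- zero_beta_truth(
    sp, list(t12 = "weibull", t13 = "weibull", t23 = "weibull"),
    list(t12 = list(shape = 1.2, scale = Inf),   # hazard identically zero
         t13 = list(shape = 1.5, scale = 40), t23 = list(shape = 1, scale = 5)))
  g <- generate_cohort(synthetic_config(n = 2000, seed = 3, truth = truth,
                                        spec = sp))
  expect_equal(sum(g$cohort$cf_event), 0)
})

test_that("simulated death times follow the configured Weibull law", {
  sp <- synth_spec()
  shp <- 1.4; scl <- 18
  truth <- zero_beta_truth(
    sp, list(t12 = "weibull", t13 = "weibull", t23 = "weibull"),
    list(t12 = list(shape = 1, scale = Inf),
         t13 = list(shape = shp, scale = scl), t23 = list(shape = 1, scale = 5)))
  cfg <- synthetic_config(n = 5000, seed = 19, truth = truth, spec = sp,
                          censoring = list(admin = 15, ltfu_max = 1e9))
  g <- generate_cohort(cfg)
  obs <- g$cohort$death_time[g$cohort$death_event == 1]
  # deaths within the horizon follow the Weibull truncated to [0, 15]
  F15 <- pweibull(15, shp, scl)
  ks <- suppressWarnings(stats::ks.test(obs, function(q)
    pweibull(q, shp, scl) / F15))
  expect_gt(ks$p.value, 0.01)
})

test_that("missingness mechanisms hit their configured rates", {
  g <- small_synth(n = 10000, seed = 55)
  # rate 0 leaves the cohort unchanged
  none <- lapply(default_missingness(), function(m) {
    m$rate[] <- 0; m
  })
  expect_identical(apply_missingness(g$cohort, none)[, names(none)],
                   g$cohort[, names(none)])
  # MCAR at 0.35 within 3 binomial SEs
  m <- list(gland_volume = list(mechanism = "mcar", rate = 0.35))
  masked <- apply_missingness(g$cohort, m)
  expect_lt(abs(mean(is.na(masked$gland_volume)) - 0.35),
            3 * sqrt(0.35 * 0.65 / 10000))
  # MAR on CCI ordered by arm as configured
  m <- list(cci = list(mechanism = "mar_treatment",
                       rate = c(surgery = 0.244, radiotherapy = 0.015)))
  masked <- apply_missingness(g$cohort, m)
  r_s <- mean(is.na(masked$cci[masked$treatment == "surgery"]))
  r_r <- mean(is.na(masked$cci[masked$treatment == "radiotherapy"]))
  expect_gt(r_s, r_r)
  expect_lt(abs(r_s - 0.244), 3 * sqrt(0.244 * 0.756 / sum(g$cohort$treatment == "surgery")))
  # original values are retained for recovery checks
  expect_identical(attr(masked, "complete_values")$cci, g$cohort$cci)
  # masking an always-observed MAR predictor is a config error
  expect_error(
    apply_missingness(g$cohort, list(treatment = list(mechanism = "mcar", rate = 0.1))),
    "unmaskable")
})

test_that("the average log-likelihood peaks near the generating parameters", {
  cfg <- synthetic_config(n = 5000, seed = 9)
  g <- generate_cohort(cfg)
  enc <- encode_cohort(g$cohort, cfg$spec)
  slice <- function(d) {
    tp <- g$truth$t13
    tp$beta["treatment_rt"] <- tp$beta["treatment_rt"] + d
    bayesidm:::.transition_loglik(tp, enc$t13)
  }
  expect_gt(slice(0), slice(0.6))
  expect_gt(slice(0), slice(-0.6))
})
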