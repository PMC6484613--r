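test_that("invalid chain configuration is rejected", {
  expect_error(idm_control(iters = 100, burn_in = 100), "must exceed")
  expect_error(idm_control(iters = 50, burn_in = 100), "must exceed")
  expect_error(idm_priors(beta_sd = 0), "beta_sd > 0")
})

test_that("the chain is exactly reproducible given the seed", {
  g <- small_synth(n = 250, seed = 4)
  co <- apply_missingness(g$cohort, synthetic_config(n = 250, seed = 4))
  ctl <- idm_control(iters = 260, burn_in = 50, thin = 1, refit_every = 50)
  f1 <- suppressWarnings(idm_bayes(co, spec = g$spec, control = ctl, seed = 31))
  f2 <- suppressWarnings(idm_bayes(co, spec = g$spec, control = ctl, seed = 31))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(idm_bayes(co, spec = g$spec, control = ctl, seed = 32))
  expect_false(identical(f3$draws, f1$draws))
})

test_that("the sampled posterior matches the conjugate Gamma closed form", {
  # exponential baseline, no covariates, Gamma(a0, b0) prior on each rate:
  # the exact posterior for a transition with D events and exposure T is
  # Gamma(a0 + D, b0 + T)
  g <- small_synth(n = 500, seed = 13)
  sp <- conj_spec()
  a0 <- 2; b0 <- 10
  fit <- idm_bayes(g$cohort, spec = sp,
                   priors = idm_priors(rate_gamma = c(a0, b0)),
                   control = idm_control(iters = 6000, burn_in = 1000, thin = 1),
                   seed = 2)
  enc <- encode_cohort(g$cohort, sp)
  for (tr in c("t12", "t13", "t23")) {
    D <- sum(enc[[tr]]$ev); Tt <- sum(enc[[tr]]$t)
    rate_draws <- exp(fit$draws[, paste0(tr, ":log_rate")])
    post_mean <- (a0 + D) / (b0 + Tt)
    post_var <- (a0 + D) / (b0 + Tt)^2
    n_eff <- ess(rate_draws)
    mcse_mean <- sd(rate_draws) / sqrt(n_eff)
    expect_lt(abs(mean(rate_draws) - post_mean), 3 * mcse_mean)
    # MCSE of the variance via batch means on the squared deviations
    dev2 <- (rate_draws - mean(rate_draws))^2
    mcse_var <- sd(dev2) / sqrt(ess(dev2))
    expect_lt(abs(var(rate_draws) - post_var), 3 * mcse_var)
  }
})

test_that("zero subjects reproduce the priors (prior-only sampling)", {
  sp <- null_spec()
  # heavy thinning so the KS test sees effectively independent draws;
  # distinct prior SDs so each marginal is identifiable
  fit <- suppressWarnings(idm_bayes(toy_cohort()[0, ], spec = sp,
                   priors = idm_priors(beta_sd = 1,
                                       beta_sd_overrides = c(treatment_rt = 2.5)),
                   control = idm_control(iters = 31000, burn_in = 1000, thin = 15),
                   seed = 6))
  # treatment coefficient: weakly-informative default N(0, 2.5)
  d_trt <- fit$draws[, "t12:treatment_rt"]
  expect_gt(suppressWarnings(ks.test(d_trt, "pnorm", 0, 2.5))$p.value, 0.01)
  # cf-time coefficient: the unit-scale shrinkage prior
  d_cf <- fit$draws[, "t23:cftime15"]
  expect_gt(suppressWarnings(ks.test(d_cf, "pnorm", 0, 1))$p.value, 0.01)
})

test_that("stronger shrinkage pulls a coefficient toward zero monotonically", {
  g <- small_synth(n = 400, seed = 17)
  ctl <- idm_control(iters = 1200, burn_in = 400, thin = 2)
  post_mean <- function(sd_trt) {
    fit <- idm_bayes(g$cohort, spec = g$spec,
                     priors = idm_priors(beta_sd_overrides = c(treatment_rt = sd_trt)),
                     control = ctl, seed = 20)
    mean(fit$draws[, "t13:treatment_rt"])
  }
  m_tight <- post_mean(0.02)
  m_mid <- post_mean(0.3)
  m_wide <- post_mean(2.5)
  expect_lt(abs(m_tight), 0.05)
  expect_lt(abs(m_tight), abs(m_mid))
  expect_lt(abs(m_mid), abs(m_wide) + 0.02)
})

test_that("a transition without events warns and stays prior-dominated", {
  g <- small_synth(n = 150, seed = 23)
  co <- g$cohort
  # censor everyone before any CF: no 1->2 or 2->3 events
  co$death_event[co$cf_event == 1] <- 0
  co$death_time[co$cf_event == 1] <- co$cf_time[co$cf_event == 1]
  co$cf_event[] <- 0
  expect_warning(
    fit <- idm_bayes(validate_cohort(as.data.frame(co)), spec = g$spec,
                     control = idm_control(iters = 400, burn_in = 100),
                     seed = 2),
    "prior-dominated")
  expect_true(all(is.finite(fit$draws)))
})

test_that("posterior HR summaries are order statistics of the draws", {
  set.seed(1)
  draws <- cbind("t12:treatment_rt" = rnorm(400, 0.2, 0.3),
                 "t12:rt_x_age10" = rnorm(400, 0, 0.1),
                 "t12:age10" = rnorm(400, 0.5, 0.2),
                 "t12:log_shape" = rnorm(400),
                 "t12:log_scale" = rnorm(400))
  tab <- summarize_posterior(draws)
  r <- tab[tab$term == "treatment_rt", ]
  h <- exp(draws[, "t12:treatment_rt"])
  expect_equal(r$hr, mean(h))
  expect_equal(r$lower, unname(quantile(h, 0.025)))
  expect_equal(r$upper, unname(quantile(h, 0.975)))
  # interaction contrast: per-arm HR sums draw columns before exponentiation
  a <- tab[tab$term == "age10" & tab$arm == "radiotherapy", ]
  h2 <- exp(draws[, "t12:age10"] + draws[, "t12:rt_x_age10"])
  expect_equal(a$hr, mean(h2))
  # degenerate chain: constant coefficient gives zero-width interval at e^c
  dg <- draws; dg[, "t12:age10"] <- 0.7
  tg <- summarize_posterior(dg)
  s <- tg[tg$term == "age10" & tg$arm == "surgery", ]
  expect_equal(c(s$hr, s$lower, s$upper), rep(exp(0.7), 3))
  # unknown contrast labels are an error
  expect_error(summarize_posterior(draws, contrasts = list(x = c(nope = 1))),
               "unknown label")
})

test_that("baseline-hazard families can differ by transition", {
  g <- small_synth(n = 300, seed = 41)
  sp <- g$spec
  sp$baseline <- list(t12 = "piecewise", t13 = "weibull", t23 = "exponential")
  fit <- idm_bayes(g$cohort, spec = sp,
                   control = idm_control(iters = 300, burn_in = 100), seed = 3)
  expect_true(any(grepl("^t12:log_h", colnames(fit$draws))))
  expect_true("t13:log_shape" %in% colnames(fit$draws))
  expect_true("t23:log_rate" %in% colnames(fit$draws))
  p <- draw_params(fit, colMeans = TRUE)
  expect_s3_class(p$t12, "idm_transition")
  expect_equal(p$t12$family, "piecewise")
})
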