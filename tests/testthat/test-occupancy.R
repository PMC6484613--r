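# a moderate-risk profile used across the occupancy tests
occ_profile <- function() {
  data.frame(age = 65, gland_volume = 40, psa = 10, cci = "1",
             gleason = "7=4+3", pni = 1, ct = "2", race = "White",
             tx_year = "2007-2013", treatment = "surgery",
             stringsAsFactors = FALSE)
}

occ_params <- function(seed = 10) {
  set.seed(seed)
  sp <- synth_spec()
  tr <- default_truth(sp)
  tr
}

test_that("occupancy starts in state 1 and stays on the probability simplex", {
  sp <- synth_spec()
  oc <- occupancy(default_truth(sp), occ_profile(), sp,
                  t_grid = seq(0, 15, by = 0.01))
  expect_equal(unlist(oc[1, 2:5]), c(p_alive_no_cf = 1, p_alive_cf = 0,
                                     p_dead_cf = 0, p_dead_no_cf = 0))
  tot <- rowSums(oc[, 2:5])
  expect_lt(max(abs(tot - 1)), 1e-6)
  # nonnegativity and monotonicity up to quadrature noise in the P2/P3 split
  expect_true(all(oc[, 2:5] >= -5e-6 & oc[, 2:5] <= 1 + 5e-6))
  expect_true(all(diff(oc$p_alive_no_cf) <= 1e-12))
  expect_true(all(diff(oc$p_dead_cf) >= -5e-6))
  expect_true(all(diff(oc$p_dead_no_cf) >= -1e-12))
})

test_that("a null illness transition reduces occupancy to plain survival", {
  sp <- synth_spec()
  pars <- default_truth(sp)
  pars$t12$scale <- Inf  # 1->2 hazard identically zero
  oc <- occupancy(pars, occ_profile(), sp, t_grid = seq(0, 15, by = 0.01))
  x13 <- encode_design_row(
    data.frame(occ_profile(), id = "p", cf_time = 0, cf_event = 0,
               death_time = 0, death_event = 0), sp, "t13")
  S13 <- survival_prob(pars$t13, oc$time, matrix(rep(x13, each = nrow(oc)),
                                                 nrow = nrow(oc)))
  expect_equal(oc$p_alive_no_cf, S13, tolerance = 1e-9)
  expect_equal(oc$p_dead_no_cf, 1 - S13, tolerance = 1e-5)
  expect_lt(max(oc$p_alive_cf), 1e-12)      # no paths into CF at all
  expect_lt(max(abs(oc$p_dead_cf)), 1e-5)   # complement, quadrature noise only
})

test_that("halving the grid step changes the curves below 1e-4", {
  sp <- synth_spec()
  pars <- default_truth(sp)
  oc1 <- occupancy(pars, occ_profile(), sp, t_grid = seq(0, 15, by = 0.02))
  oc2 <- occupancy(pars, occ_profile(), sp, t_grid = seq(0, 15, by = 0.01))
  sub <- seq(1, nrow(oc2), by = 2)
  for (cl in names(oc1)[2:5])
    expect_lt(max(abs(oc1[[cl]] - oc2[[cl]][sub])), 1e-4)
})

test_that("analytic curves match Monte-Carlo trajectory frequencies", {
  # small-n version of the trajectory oracle (the full 200k-path check runs
  # in the acceptance suite): random bounded-hazard Weibull parameters
  set.seed(5)
  sp <- synth_spec()
  pars <- list(
    t12 = transition_params("weibull", shape = runif(1, 1, 2),
                            scale = runif(1, 8, 30),
                            beta = default_truth(sp)$t12$beta),
    t13 = transition_params("weibull", shape = runif(1, 1, 2.5),
                            scale = runif(1, 15, 50),
                            beta = default_truth(sp)$t13$beta),
    t23 = transition_params("weibull", shape = runif(1, 1, 1.6),
                            scale = runif(1, 2, 8),
                            beta = default_truth(sp)$t23$beta))
  oc <- occupancy(pars, occ_profile(), sp, t_grid = seq(0, 15, by = 0.01))
  emp <- bayesidm:::.simulate_occupancy(pars, occ_profile(), sp,
                                        n = 40000, times = c(2, 5, 10, 15))
  for (k in seq_along(emp$times)) {
    i <- which.min(abs(oc$time - emp$times[k]))
    ana <- unlist(oc[i, 2:5])
    se <- sqrt(pmax(ana * (1 - ana), 1e-6) / 40000)
    expect_true(all(abs(ana - emp$freq[k, ]) < pmax(4 * se, 0.012)),
                info = paste("t =", emp$times[k]))
  }
})

test_that("posterior occupancy bands behave and degenerate correctly", {
  g <- small_synth(n = 350, seed = 12)
  fit <- idm_bayes(g$cohort, spec = g$spec,
                   control = idm_control(iters = 700, burn_in = 200, thin = 2),
                   seed = 9)
  po <- posterior_occupancy(fit, occ_profile(), "surgery",
                            t_grid = seq(0, 15, by = 0.25), ndraws = 40)
  # mean curve inherits the simplex invariants
  tot <- rowSums(po$mean[, 2:5])
  expect_lt(max(abs(tot - 1)), 1e-6)
  expect_true(all(po$lower$p_alive_no_cf <= po$upper$p_alive_no_cf + 1e-12))
  # degenerate draws: identical parameters give coinciding bands
  fit2 <- fit
  fit2$draws <- fit$draws[rep(1, 150), ]
  po2 <- posterior_occupancy(fit2, occ_profile(), "surgery",
                             t_grid = seq(0, 15, by = 0.25), ndraws = 30)
  expect_equal(po2$lower$p_alive_cf, po2$upper$p_alive_cf, tolerance = 1e-12)
  expect_equal(po2$mean$p_alive_cf, po2$lower$p_alive_cf, tolerance = 1e-12)
})

test_that("treatment comparison is null when no transition sees treatment", {
  sp <- synth_spec()
  pars <- default_truth(sp)
  for (tr in c("t12", "t13", "t23")) pars[[tr]]$beta["treatment_rt"] <- 0
  cmp <- compare_treatments(pars, occ_profile(), spec = sp,
                            t_grid = seq(0, 15, by = 0.05), horizons = 10)
  expect_equal(cmp$surgery$p_alive_no_cf, cmp$radiotherapy$p_alive_no_cf)
  expect_equal(cmp$summary$p1_diff, 0)
  # named 10-year fields are exposed per arm
  expect_true(all(c("p1_surgery", "p1_radiotherapy", "os_surgery",
                    "os_radiotherapy") %in% names(cmp$summary)))
})

test_that("a protective radiotherapy effect on CF lowers the CF burden", {
  sp <- synth_spec()
  pars <- default_truth(sp)
  for (tr in c("t12", "t13", "t23")) pars[[tr]]$beta["treatment_rt"] <- 0
  pars$t12$beta["treatment_rt"] <- log(0.5)  # protective on 1->2 only
  cmp <- compare_treatments(pars, occ_profile(), spec = sp,
                            t_grid = seq(0, 15, by = 0.05), horizons = 10)
  cf_burden <- function(oc, t) {
    i <- which.min(abs(oc$time - t))
    oc$p_alive_cf[i] + oc$p_dead_cf[i]
  }
  expect_lt(cf_burden(cmp$radiotherapy, 10), cf_burden(cmp$surgery, 10))
})

test_that("an incomplete profile is rejected with its missing fields", {
  sp <- synth_spec()
  pr <- occ_profile()
  pr$psa <- NA
  pr$cci <- NA
  err <- tryCatch(occupancy(default_truth(sp), pr, sp), error = identity)
  expect_match(conditionMessage(err), "incomplete profile")
  expect_match(conditionMessage(err), "psa")
  expect_match(conditionMessage(err), "cci")
})
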