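# Four-state occupancy probabilities of the clock-reset illness-death model.
#
# For a covariate profile x (treatment set by the caller):
#   P1(t) = exp(-L12(t|x) - L13(t|x))                       alive, no prior CF
#   P4(t) = int_0^t P1(u) l13(u|x) du                       dead without CF
#   P2(t) = int_0^t P1(u) l12(u|x) S23(t-u | x, u/15) du    alive with CF
#   P3(t) = int_0^t P1(u) l12(u|x) [1 - S23(t-u|x,u/15)] du dead after CF
# The CF-to-death survivor inside the integrand runs on the reset clock and
# carries the time of CF entry (scaled, u/15) in its linear predictor --
# exactly as in the likelihood.  Integrals use composite Simpson weights on
# the uniform grid (a 3-point Newton-Cotes closing rule on odd segments),
# so the quadrature error is O(delta^4); the first two grid intervals are
# integrated by Gauss-Legendre in cumulative-hazard coordinates, where the
# integrand is bounded even when the hazard is singular at 0 (shape < 1).

# Simpson weights for the partial integrals 0..t_i on a uniform grid,
# returned as a lower-triangular (G x G) matrix of weights
.simpson_weight_matrix <- function(G, delta) {
  W <- matrix(0, G, G)
  if (G < 2) return(W)
  w_even <- function(m) {  # m intervals, m even: 1 4 2 ... 4 1 times d/3
    w <- rep(c(2, 4), length.out = m + 1)
    w[1] <- 1; w[m + 1] <- 1
    w * delta / 3
  }
  for (i in 2:G) {
    m <- i - 1L
    if (m == 1L) {
      W[i, 1:2] <- delta / 2
    } else if (m %% 2L == 0L) {
      W[i, 1:i] <- w_even(m)
    } else {
      W[i, 1:(i - 1)] <- w_even(m - 1L)
      # half-interval closing rule: int_{t_{m-1}}^{t_m} ~ d/12 (-f_{m-2} + 8 f_{m-1} + 5 f_m)
      W[i, i - 2L] <- W[i, i - 2L] - delta / 12
      W[i, i - 1L] <- W[i, i - 1L] + 8 * delta / 12
      W[i, i] <- W[i, i] + 5 * delta / 12
    }
  }
  W
}

# cumulative integral with the same weights; the first two values may be
# supplied exactly (integrals to delta and 2*delta), in which case the
# recursion never evaluates the integrand at 0 -- this is how hazards that
# are singular at the origin (Weibull shape < 1) are accommodated
.cumsimp <- function(f, delta, seed2 = NULL, seed3 = NULL) {
  G <- length(f)
  out <- numeric(G)
  if (G < 2) return(out)
  out[2] <- if (is.null(seed2)) delta / 2 * (f[1] + f[2]) else seed2
  if (G >= 3)
    out[3] <- if (is.null(seed3))
      out[1] + delta / 3 * (f[1] + 4 * f[2] + f[3]) else seed3
  if (G >= 4) {
    for (i in 4:G) {
      m <- i - 1L
      if (m %% 2L == 0L) {
        out[i] <- out[i - 2] + delta / 3 * (f[i - 2] + 4 * f[i - 1] + f[i])
      } else {
        out[i] <- out[i - 1] +
          delta / 12 * (-f[i - 2] + 8 * f[i - 1] + 5 * f[i])
      }
    }
  }
  out
}

# 8-point Gauss-Legendre nodes/weights on [0, 1]
.gl8 <- list(
  x = c(0.01985507175123188, 0.10166676129318664, 0.2372337950418355,
        0.40828267875217505, 0.5917173212478249, 0.7627662049581645,
        0.8983332387068134, 0.9801449282487681),
  w = c(0.05061426814518813, 0.11119051722668724, 0.15685332293894363,
        0.18134189168918097, 0.18134189168918097, 0.15685332293894363,
        0.11119051722668724, 0.05061426814518813))

.check_grid <- function(t_grid) {
  if (length(t_grid) < 3 || t_grid[1] != 0)
    stop("t_grid must be a uniform grid starting at 0")
  d <- diff(t_grid)
  if (any(abs(d - d[1]) > 1e-9)) stop("t_grid must be uniformly spaced")
  d[1]
}

.profile_complete <- function(profile, spec) {
  need <- unique(vapply(setdiff(unlist(spec$terms), "cf_time"),
                        .term_fields, ""))
  miss <- need[vapply(need, function(f)
    is.null(profile[[f]]) || is.na(profile[[f]]), TRUE)]
  if (length(miss))
    stop("incomplete profile; missing field(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Individualized four-state occupancy probabilities
#'
#' Computes, over a time grid, the probability that a patient with the given
#' baseline profile is (1) alive without prior clinical failure, (2) alive
#' with prior CF, (3) dead with prior CF, or (4) dead without prior CF,
#' under the fitted semi-Markov transition model.  `p_alive_no_cf` is
#' metastasis-free survival; `p_alive_no_cf + p_alive_cf` is overall
#' survival.
#'
#' @param params list of three [transition_params()] (`t12`, `t13`, `t23`)
#'   with coefficients aligned to `spec`'s design columns.
#' @param profile one-row data frame of baseline covariates (all fields the
#'   spec uses must be present and non-missing; outcome columns are ignored
#'   and may be absent).
#' @param spec the [idm_spec()] with frozen centering constants used at fit
#'   time.
#' @param treatment `"surgery"` or `"radiotherapy"`; overrides
#'   `profile$treatment` when given.
#' @param t_grid uniform time grid from 0 (years); default step 0.01 to 15.
#' @return data frame of class `idm_occupancy` with columns `time`,
#'   `p_alive_no_cf`, `p_alive_cf`, `p_dead_cf`, `p_dead_no_cf`;
#'   attributes `treatment` and `provenance`.
#' @export
occupancy <- function(params, profile, spec, treatment = NULL,
                      t_grid = seq(0, 15, by = 0.01)) {
  delta <- .check_grid(t_grid)
  G <- length(t_grid)
  profile <- as.data.frame(profile)[1, , drop = FALSE]
  if (!is.null(treatment)) profile$treatment <- treatment
  .profile_complete(profile, spec)
  rec <- .reference_record()
  for (f in intersect(names(profile), names(rec))) rec[[f]] <- profile[[f]]

  x12 <- encode_design_row(rec, spec, "t12")
  x13 <- encode_design_row(rec, spec, "t13")
  rec23 <- rec; rec23$cf_time <- 0
  x23_0 <- encode_design_row(rec23, spec, "t23")
  rec23$cf_time <- 15  # cftime15 column becomes 1
  x23_1 <- encode_design_row(rec23, spec, "t23")

  tp12 <- params$t12; tp13 <- params$t13; tp23 <- params$t23
  L12 <- .base_cumhaz(tp12, t_grid) * exp(sum(x12 * tp12$beta))
  L13 <- .base_cumhaz(tp13, t_grid) * exp(sum(x13 * tp13$beta))
  P1 <- exp(-L12 - L13)

  lp12 <- sum(x12 * tp12$beta)
  lp13 <- sum(x13 * tp13$beta)
  P1_at <- function(u) exp(-.base_cumhaz(tp12, u) * exp(lp12) -
                             .base_cumhaz(tp13, u) * exp(lp13))
  # hazards at positive grid times; the origin node is never used because
  # the first two intervals are integrated in transformed coordinates
  f13 <- c(0, P1[-1] * exp(.base_loghaz(tp13, t_grid[-1]) + lp13))
  f12 <- c(0, P1[-1] * exp(.base_loghaz(tp12, t_grid[-1]) + lp12))

  # linear predictor of 2->3 at CF time u: lp23(u) = x'b at u=0 plus the
  # cf-time slope (including its treatment interaction) times u/15
  b23 <- tp23$beta
  lp0 <- sum(x23_0 * b23)
  slope <- sum((x23_1 - x23_0) * b23)  # coefficient on u/15 terms
  S23_at <- function(v, u)  # reset-clock survivor, CF entry at u
    exp(-.base_cumhaz(tp23, pmax(v, 0)) * exp(lp0 + slope * u / 15))

  # int_0^U P1(u) lam_k(u|x) g(u) du via Gauss-Legendre in w = Lambda_k(u|x):
  # the transformed integrand P1(u(w)) g(u(w)) is bounded for any shape
  sub_int <- function(tp_k, lp_k, U, g = NULL) {
    Wup <- .base_cumhaz(tp_k, U) * exp(lp_k)
    if (Wup == 0) return(0)  # null transition
    wn <- .gl8$x * Wup
    un <- .base_cumhaz_inv(tp_k, wn * exp(-lp_k))
    gv <- if (is.null(g)) 1 else g(un)
    Wup * sum(.gl8$w * P1_at(un) * gv)
  }

  P4 <- .cumsimp(f13, delta,
                 seed2 = sub_int(tp13, lp13, t_grid[2]),
                 seed3 = sub_int(tp13, lp13, t_grid[3]))
  # P2 + P3 (ever entered CF) and P4 partition 1 - P1 exactly; taking the
  # complement instead of a second quadrature makes the four states sum to
  # one identically and confines quadrature error to the P2/P3 split
  P23 <- (1 - P1) - P4

  eg <- exp(lp0 + slope * t_grid / 15)
  H23 <- .base_cumhaz(tp23, t_grid)
  idx <- pmax(outer(seq_len(G), seq_len(G), "-") + 1L, 1L)
  S23m <- exp(-matrix(H23[idx], G, G) * matrix(eg, G, G, byrow = TRUE))

  # tail of the P2 integral over [2*delta, t] on the grid rule ...
  P2 <- numeric(G)
  if (G > 3) {
    Wt <- .simpson_weight_matrix(G - 2L, delta)
    P2[3:G] <- rowSums(Wt * S23m[3:G, 3:G, drop = FALSE] *
                         matrix(f12[3:G], G - 2L, G - 2L, byrow = TRUE))
  }
  # ... plus the head over [0, min(2*delta, t)] in transformed coordinates
  head2 <- vapply(seq_len(G), function(i) {
    if (i == 1) return(0)
    U <- min(t_grid[3], t_grid[i])
    sub_int(tp12, lp12, U, g = function(u) S23_at(t_grid[i] - u, u))
  }, 0)
  P2 <- P2 + head2
  P3 <- P23 - P2

  out <- data.frame(time = t_grid, p_alive_no_cf = P1, p_alive_cf = P2,
                    p_dead_cf = P3, p_dead_no_cf = P4)
  attr(out, "treatment") <- as.character(rec$treatment)
  attr(out, "provenance") <- "point"
  class(out) <- c("idm_occupancy", "data.frame")
  out
}

# Monte-Carlo trajectory oracle: simulate n uncensored semi-Markov paths for
# one profile and tabulate state frequencies at the requested times.  Shares
# the cumulative-hazard inversion with the cohort generator.
.simulate_occupancy <- function(params, profile, spec, n = 200000,
                                times = c(2, 5, 10, 15), treatment = NULL) {
  profile <- as.data.frame(profile)[1, , drop = FALSE]
  if (!is.null(treatment)) profile$treatment <- treatment
  rec <- .reference_record()
  for (f in intersect(names(profile), names(rec))) rec[[f]] <- profile[[f]]
  x12 <- encode_design_row(rec, spec, "t12")
  x13 <- encode_design_row(rec, spec, "t13")
  rec23 <- rec; rec23$cf_time <- 0
  x23_0 <- encode_design_row(rec23, spec, "t23")
  rec23$cf_time <- 15
  x23_1 <- encode_design_row(rec23, spec, "t23")
  lp12 <- sum(x12 * params$t12$beta)
  lp13 <- sum(x13 * params$t13$beta)
  b23 <- params$t23$beta
  lp23_0 <- sum(x23_0 * b23)
  slope <- sum((x23_1 - x23_0) * b23)

  T12 <- .base_cumhaz_inv(params$t12, stats::rexp(n) * exp(-lp12))
  T13 <- .base_cumhaz_inv(params$t13, stats::rexp(n) * exp(-lp13))
  cf <- T12 < T13
  u <- ifelse(cf, T12, Inf)
  lp23 <- lp23_0 + slope * pmin(u, 15) / 15
  V <- .base_cumhaz_inv(params$t23, stats::rexp(n) * exp(-lp23))
  death <- ifelse(cf, T12 + V, T13)
  freq <- t(vapply(times, function(tt) {
    s1 <- !cf & tt < T13 | cf & tt < T12
    s2 <- cf & tt >= T12 & tt < death
    s3 <- cf & tt >= death
    s4 <- !cf & tt >= T13
    c(mean(s1), mean(s2), mean(s3), mean(s4))
  }, numeric(4)))
  list(times = times, freq = freq)
}

#' Posterior-averaged occupancy with pointwise credible bands
#'
#' Recomputes the occupancy curves for a thinned subset of posterior draws
#' and returns the pointwise mean curve together with equal-tailed 2.5/97.5
#' percentile bands for each state.
#'
#' @param fit an `idm_fit` (needs >= 100 retained draws).
#' @param profile,treatment,t_grid as in [occupancy()] (default grid step
#'   0.05 y for the per-draw sweep).
#' @param ndraws number of (evenly thinned) draws to propagate.
#' @return list of class `idm_occupancy_post` with elements `mean`, `lower`,
#'   `upper` (each an `idm_occupancy` frame) and `ndraws`.
#' @export
posterior_occupancy <- function(fit, profile, treatment = NULL,
                                t_grid = seq(0, 15, by = 0.05), ndraws = 100) {
  S <- nrow(fit$draws)
  if (S < 100) stop("need at least 100 post-burn-in draws")
  use <- unique(round(seq(1, S, length.out = min(ndraws, S))))
  G <- length(t_grid)
  arr <- array(NA_real_, c(length(use), G, 4))
  for (k in seq_along(use)) {
    oc <- occupancy(draw_params(fit, use[k]), profile, fit$spec,
                    treatment = treatment, t_grid = t_grid)
    arr[k, , ] <- as.matrix(oc[, 2:5])
  }
  mk <- function(M, prov) {
    out <- data.frame(time = t_grid, p_alive_no_cf = M[, 1],
                      p_alive_cf = M[, 2], p_dead_cf = M[, 3],
                      p_dead_no_cf = M[, 4])
    attr(out, "treatment") <- if (is.null(treatment))
      as.character(profile$treatment) else treatment
    attr(out, "provenance") <- prov
    class(out) <- c("idm_occupancy", "data.frame")
    out
  }
  structure(list(
    mean = mk(apply(arr, c(2, 3), mean), "posterior-mean"),
    lower = mk(apply(arr, c(2, 3), stats::quantile, 0.025), "posterior-2.5%"),
    upper = mk(apply(arr, c(2, 3), stats::quantile, 0.975), "posterior-97.5%"),
    ndraws = length(use)), class = "idm_occupancy_post")
}

#' Compare predicted outcomes under surgery versus radiotherapy
#'
#' Computes the occupancy curves for the same baseline profile under both
#' treatments (at the posterior-mean parameters of a fit, or at supplied
#' parameters) and summarizes per-arm probabilities at requested horizons --
#' e.g. the 10-year probability of being alive and disease-free per arm.
#'
#' @param fit an `idm_fit`, or a list of three [transition_params()] (then
#'   `spec` must be supplied).
#' @param profile one-row baseline profile.
#' @param t_grid uniform grid from 0.
#' @param horizons times (years) at which per-arm summaries are reported.
#' @param spec required when `fit` is a raw parameter list.
#' @return list of class `idm_treatment_comparison`: `surgery`,
#'   `radiotherapy` (occupancy frames) and `summary` (data frame with
#'   `horizon`, `p1_surgery`, `p1_radiotherapy`, `p1_diff`,
#'   `os_surgery`, `os_radiotherapy`, `os_diff`).
#' @export
compare_treatments <- function(fit, profile, t_grid = seq(0, 15, by = 0.01),
                               horizons = 10, spec = NULL) {
  if (inherits(fit, "idm_fit")) {
    params <- draw_params(fit, colMeans = TRUE)
    spec <- fit$spec
  } else {
    params <- fit
    if (is.null(spec)) stop("supply spec with raw parameters")
  }
  if (!any(vapply(spec$terms, function(tt) "treatment" %in% tt, TRUE)))
    stop("treatment term absent from the model")
  oc_s <- occupancy(params, profile, spec, "surgery", t_grid)
  oc_r <- occupancy(params, profile, spec, "radiotherapy", t_grid)
  at <- function(oc, h, col) oc[[col]][which.min(abs(oc$time - h))]
  summ <- do.call(rbind, lapply(horizons, function(h) {
    p1s <- at(oc_s, h, "p_alive_no_cf"); p1r <- at(oc_r, h, "p_alive_no_cf")
    oss <- p1s + at(oc_s, h, "p_alive_cf")
    osr <- p1r + at(oc_r, h, "p_alive_cf")
    data.frame(horizon = h, p1_surgery = p1s, p1_radiotherapy = p1r,
               p1_diff = p1s - p1r, os_surgery = oss, os_radiotherapy = osr,
               os_diff = oss - osr)
  }))
  structure(list(surgery = oc_s, radiotherapy = oc_r, summary = summ),
            class = "idm_treatment_comparison")
}

#' @export
print.idm_treatment_comparison <- function(x, ...) {
  cat("Predicted state occupancy: surgery vs radiotherapy\n")
  y <- x$summary
  for (i in seq_len(nrow(y))) {
    cat(sprintf("  %g-y alive & disease-free: surgery %.0f%%, radiotherapy %.0f%%\n",
                y$horizon[i], 100 * y$p1_surgery[i], 100 * y$p1_radiotherapy[i]))
    cat(sprintf("  %g-y overall survival:     surgery %.0f%%, radiotherapy %.0f%%\n",
                y$horizon[i], 100 * y$os_surgery[i], 100 * y$os_radiotherapy[i]))
  }
  invisible(x)
}

#' Stacked-area plot of occupancy curves
#'
#' @param x an `idm_occupancy`.
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.idm_occupancy <- function(x, main = NULL, ...) {
  t <- x$time
  c1 <- x$p_alive_no_cf
  c2 <- c1 + x$p_alive_cf
  c3 <- c2 + x$p_dead_cf
  cols <- c("#4daf4a", "#ffb000", "#e41a1c", "#777777")
  if (is.null(main))
    main <- paste("State occupancy,", attr(x, "treatment"))
  graphics::plot(NULL, xlim = range(t), ylim = c(0, 1), xlab = "Years",
                 ylab = "Probability", main = main)
  band <- function(lo, hi, col)
    graphics::polygon(c(t, rev(t)), c(lo, rev(hi)), col = col, border = NA)
  band(rep(0, length(t)), c1, cols[1])
  band(c1, c2, cols[2])
  band(c2, c3, cols[3])
  band(c3, rep(1, length(t)), cols[4])
  graphics::legend("bottomleft",
                   legend = c("Alive, no CF", "Alive after CF",
                              "Dead after CF", "Dead, no CF"),
                   fill = cols, bg = "white", cex = 0.8)
  invisible(x)
}

#' Predict method: individualized occupancy from a fitted model
#'
#' @param object an `idm_fit`.
#' @param profile one-row baseline covariate profile.
#' @param treatment `"surgery"`, `"radiotherapy"`, or `"both"` (default:
#'   compare both arms via [compare_treatments()]).
#' @param t_grid uniform time grid.
#' @param posterior if `TRUE`, propagate posterior uncertainty via
#'   [posterior_occupancy()] (single-arm only).
#' @param ... passed on.
#' @return an `idm_occupancy`, `idm_occupancy_post`, or
#'   `idm_treatment_comparison`.
#' @export
predict.idm_fit <- function(object, profile, treatment = "both",
                            t_grid = seq(0, 15, by = 0.01),
                            posterior = FALSE, ...) {
  if (identical(treatment, "both"))
    return(compare_treatments(object, profile, t_grid, ...))
  if (posterior)
    return(posterior_occupancy(object, profile, treatment, t_grid, ...))
  occupancy(draw_params(object, colMeans = TRUE), profile, object$spec,
            treatment, t_grid)
}
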