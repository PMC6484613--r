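# Chained-equations imputation embedded in the MCMC.
#
# Conditional models per maskable field, each regressing on every other
# covariate (at its current imputed value) plus survival-outcome summaries
# (event indicators and log follow-up terms), cycled once per call:
#   - log gland volume, log PSA: Bayesian normal linear regression; proper
#     draws (coefficients and residual variance drawn, residual noise added)
#   - PNI: logistic regression, coefficient vector drawn from its asymptotic
#     normal, then a Bernoulli draw
#   - CCI, Gleason, cT, race: multinomial logistic conditionals
#     (nnet::multinom), category sampled from the predicted probabilities
# Singular conditional models fall back to a ridge-stabilized solve with a
# warning.

.field_kind <- function(f) {
  switch(f, gland_volume = "lognormal", psa = "lognormal", pni = "binary",
         cci = "categorical", gleason = "categorical", ct = "categorical",
         race = "categorical", stop("field not imputable: ", f))
}

# imputation predictors: every covariate term except those derived from the
# target field, plus the outcome summaries
.impute_predictors <- function(cohort, spec, field, zout) {
  all_terms <- c("treatment", "age", "log_psa", "log_volume", "cci",
                 "gleason", "pni", "ct", "race", "tx_year")
  use <- all_terms[vapply(all_terms, .term_fields, "") != field]
  cols <- lapply(use, .term_cols, df = cohort, ctr = spec$centering)
  cbind(do.call(cbind, cols), zout)
}

.imputation_prepare <- function(cohort, spec, control) {
  fields <- intersect(.maskable_fields, names(cohort))
  fields <- fields[vapply(fields, function(f) anyNA(cohort[[f]]), TRUE)]
  # restrict to fields the model actually uses
  needed <- unique(vapply(unlist(spec$terms), .term_fields, ""))
  fields <- intersect(fields, needed)
  miss_idx <- lapply(fields, function(f) which(is.na(cohort[[f]])))
  names(miss_idx) <- fields
  for (f in fields) {
    if (length(miss_idx[[f]]) == nrow(cohort))
      stop("field '", f, "' is missing for all subjects; ",
           "its conditional imputation model is inestimable")
  }
  # outcome summaries entering every conditional (static over the chain)
  zout <- NULL
  if (nrow(cohort) > 0) {
    v <- pmax(cohort$death_time - cohort$cf_time, 0)
    zout <- cbind(cf_event = cohort$cf_event,
                  death_event = cohort$death_event,
                  log_t1 = log(cohort$cf_time + 0.01),
                  cf_log_v = cohort$cf_event * log1p(v))
  }
  # initial fill: observed mean (log scale) or a draw from observed categories
  for (f in fields) {
    ix <- miss_idx[[f]]
    obs <- cohort[[f]][-ix]
    if (.field_kind(f) == "lognormal") {
      cohort[[f]][ix] <- exp(mean(log(obs)))
    } else if (.field_kind(f) == "binary") {
      cohort[[f]][ix] <- stats::rbinom(length(ix), 1, mean(obs == 1))
    } else {
      tab <- table(droplevels(factor(obs)))
      cohort[[f]][ix] <- sample(names(tab), length(ix), replace = TRUE,
                                prob = tab / sum(tab))
    }
  }
  list(cohort = cohort, fields = fields, miss_idx = miss_idx,
       zout = zout, cache = list())
}

# ridge-stabilized Bayesian linear regression draw
.bayes_lm_draw <- function(Z, y, Zm) {
  Z1 <- cbind(1, Z); Zm1 <- cbind(1, Zm)
  p <- ncol(Z1)
  A <- crossprod(Z1)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-8)) {
    warning("singular imputation conditional; ridge-stabilized")
    A <- A + diag(1e-4 * (diag(A) + 1), p)
    ch <- chol(A)
  }
  bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(Z1, y)))
  rss <- sum((y - Z1 %*% bhat)^2)
  df <- max(length(y) - p, 2)
  sig2 <- rss / stats::rchisq(1, df)
  bstar <- bhat + sqrt(sig2) * backsolve(ch, stats::rnorm(p))
  drop(Zm1 %*% bstar) + stats::rnorm(nrow(Zm1), 0, sqrt(sig2))
}

.softmax_rows <- function(E) {
  E <- exp(E - apply(E, 1, max))
  E / rowSums(E)
}

# one chained-equations cycle; refit = refit categorical/binary conditionals
.impute_cycle <- function(istate, spec, refit) {
  cohort <- istate$cohort
  cache <- istate$cache
  for (f in istate$fields) {
    ix <- istate$miss_idx[[f]]
    Z <- .impute_predictors(cohort, spec, f, istate$zout)
    Zo <- Z[-ix, , drop = FALSE]; Zm <- Z[ix, , drop = FALSE]
    kind <- .field_kind(f)
    if (kind == "lognormal") {
      y <- log(cohort[[f]][-ix])
      cohort[[f]][ix] <- exp(.bayes_lm_draw(Zo, y, Zm))
    } else if (kind == "binary") {
      if (refit || is.null(cache[[f]])) {
        yo <- cohort[[f]][-ix]
        fit <- tryCatch(
          suppressWarnings(stats::glm.fit(cbind(1, Zo), yo,
                                          family = stats::binomial())),
          error = function(e) NULL)
        if (is.null(fit) || !fit$converged ||
            any(!is.finite(fit$coefficients))) {
          warning("binary imputation conditional unstable; ",
                  "falling back to the marginal rate")
          cache[[f]] <- list(marginal = mean(yo == 1))
        } else {
          w <- fit$weights
          A <- crossprod(cbind(1, Zo) * sqrt(w))
          ch <- tryCatch(chol(A), error = function(e) {
            warning("singular imputation conditional; ridge-stabilized")
            chol(A + diag(1e-4 * (diag(A) + 1), ncol(A)))
          })
          cache[[f]] <- list(coef = fit$coefficients, chol = ch)
        }
      }
      cf <- cache[[f]]
      p <- if (!is.null(cf$marginal)) rep(cf$marginal, length(ix)) else {
        bstar <- cf$coef + backsolve(cf$chol, stats::rnorm(length(cf$coef)))
        stats::plogis(drop(cbind(1, Zm) %*% bstar))
      }
      cohort[[f]][ix] <- as.numeric(stats::runif(length(ix)) < p)
    } else {  # categorical
      if (refit || is.null(cache[[f]])) {
        yo <- droplevels(factor(cohort[[f]][-ix]))
        if (nlevels(yo) < 2) {
          cache[[f]] <- list(single = levels(yo))
        } else {
          dat <- data.frame(y = yo, Zo)
          fit <- nnet::multinom(y ~ ., data = dat, trace = FALSE, maxit = 80,
                                MaxNWts = 5000)
          W <- stats::coef(fit)
          if (is.null(dim(W))) W <- matrix(W, nrow = 1)
          cache[[f]] <- list(W = W, levels = levels(yo))
        }
      }
      cf <- cache[[f]]
      if (!is.null(cf$single)) {
        cohort[[f]][ix] <- cf$single
      } else {
        eta <- cbind(0, cbind(1, Zm) %*% t(cf$W))
        P <- .softmax_rows(eta)
        u <- stats::runif(length(ix))
        cum <- t(apply(P, 1, cumsum))
        picks <- 1L + rowSums(cum < u)
        cohort[[f]][ix] <- cf$levels[pmin(picks, length(cf$levels))]
      }
    }
  }
  istate$cohort <- cohort
  istate$cache <- cache
  istate
}

#' One chained-equations imputation cycle
#'
#' Cycles once through every covariate field with missing values, drawing
#' each from its conditional model given the other covariates (at their
#' current values) and the outcome summaries.  Exposed for testing and for
#' standalone multiple imputation; within [idm_bayes()] the cycle runs every
#' iteration of the chain.
#'
#' @param cohort cohort data frame with `NA`s in imputable fields.
#' @param spec an [idm_spec()] (centering frozen from the cohort if needed).
#' @param state optional state returned by a previous call (to reuse fitted
#'   conditionals); if `NULL` the conditionals are (re)fitted.
#' @return list with `cohort` (missing values filled) and `state`.
#' @export
impute_step <- function(cohort, spec = idm_spec(), state = NULL) {
  if (!anyNA(cohort[, intersect(.maskable_fields, names(cohort))]))
    return(list(cohort = cohort, state = state))
  spec <- freeze_centering(spec, cohort)
  if (is.null(state)) {
    state <- .imputation_prepare(cohort, spec, NULL)
    state <- .impute_cycle(state, spec, refit = TRUE)
  } else {
    state <- .impute_cycle(state, spec, refit = FALSE)
  }
  list(cohort = state$cohort, state = state)
}
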