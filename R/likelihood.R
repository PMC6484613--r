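#' Encode a cohort for likelihood evaluation
#'
#' Builds, per transition, the design matrix, the time at risk and the event
#' indicator used by the semi-Markov likelihood.  Time at risk in the
#' initial state is the CF time (equal to the follow-up time for subjects
#' without CF); the CF-to-death transition runs on the reset clock, with
#' sojourn `v = death_time - cf_time` (a same-day CF and death is assigned
#' the spec's `epsilon` sojourn), and only CF subjects contribute.
#'
#' @param cohort cohort data frame with complete covariates for the spec's
#'   terms (impute first if needed).
#' @param spec an [idm_spec()]; centering constants are frozen from the
#'   cohort if not already set.
#' @return list with `spec` (frozen) and elements `t12`, `t13`, `t23`, each
#'   holding `X`, `t`, `ev` and the subject ids.
#' @export
encode_cohort <- function(cohort, spec) {
  spec <- freeze_centering(spec, cohort)
  t1 <- cohort$cf_time
  out <- list(spec = spec)
  out$t12 <- list(X = design_matrix(cohort, spec, "t12"), t = t1,
                  ev = as.numeric(cohort$cf_event), id = cohort$id)
  out$t13 <- list(X = design_matrix(cohort, spec, "t13"), t = t1,
                  ev = as.numeric(cohort$death_event) * (1 - cohort$cf_event),
                  id = cohort$id)
  cf <- cohort$cf_event == 1
  sub <- cohort[cf, , drop = FALSE]
  v <- sub$death_time - sub$cf_time
  if (any(v < 0)) stop("negative post-CF sojourn for id ",
                       sub$id[which(v < 0)[1]])
  v[v == 0] <- spec$epsilon
  out$t23 <- list(X = design_matrix(sub, spec, "t23"), t = v,
                  ev = as.numeric(sub$death_event), id = sub$id)
  out
}

# log-likelihood of one transition given its encoded data
.transition_loglik <- function(tp, dat) {
  if (length(dat$t) == 0) return(0)
  lp <- .lp(tp, dat$X)
  H <- .base_cumhaz(tp, dat$t) * exp(lp)
  ll <- -sum(H)
  ev <- dat$ev == 1
  if (any(ev)) ll <- ll + sum(.base_loghaz(tp, dat$t[ev]) + lp[ev])
  if (!is.finite(ll)) {
    contrib <- -H
    contrib[ev] <- contrib[ev] + .base_loghaz(tp, dat$t[ev]) + lp[ev]
    bad <- which(!is.finite(contrib))
    stop("non-finite likelihood contribution for id ",
         paste(utils::head(dat$id[bad], 3), collapse = ", "))
  }
  ll
}

#' Semi-Markov illness-death log-likelihood
#'
#' Sums, over subjects, the three transition contributions of the
#' clock-reset illness-death model.  A subject without CF observed to
#' follow-up time T contributes \eqn{\log S_{12}(T|x) + \log S_{13}(T|x) +
#' d \log\lambda_{13}(T|x)} (d the death indicator); a subject with CF at u
#' and post-CF follow-up v contributes \eqn{\log S_{12}(u|x) +
#' \log\lambda_{12}(u|x) + \log S_{13}(u|x) + \log S_{23}(v|x,u/15) + d
#' \log\lambda_{23}(v|x,u/15)}.  The 1->3 contribution of a CF subject uses
#' survival only to u: death after CF is never counted as death from other
#' causes.
#'
#' @param params list with `t12`, `t13`, `t23` [transition_params()] whose
#'   `beta` align with the encoded design columns.
#' @param encoded result of [encode_cohort()] (or a cohort data frame, in
#'   which case `spec` must be given).
#' @param spec an [idm_spec()], only when `encoded` is a raw cohort.
#' @return scalar log-likelihood (0 for an empty cohort).
#' @export
log_likelihood <- function(params, encoded, spec = NULL) {
  if (is.data.frame(encoded)) {
    if (is.null(spec)) stop("supply a spec when passing a raw cohort")
    if (nrow(encoded) == 0) return(0)
    encoded <- encode_cohort(encoded, spec)
  }
  .transition_loglik(params$t12, encoded$t12) +
    .transition_loglik(params$t13, encoded$t13) +
    .transition_loglik(params$t23, encoded$t23)
}
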