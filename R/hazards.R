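#' Parameters of one transition submodel
#'
#' A proportional-hazards transition intensity \eqn{\lambda(t | x) =
#' \lambda_0(t) \exp(x'\beta)} with a Weibull, piecewise-exponential, or
#' exponential baseline.  The Weibull baseline is parameterized as
#' \eqn{\lambda_0(t) = (\alpha/b)(t/b)^{\alpha-1}} (shape \eqn{\alpha},
#' scale \eqn{b}), so \eqn{\Lambda_0(t) = (t/b)^\alpha}; the exponential is
#' the \eqn{\alpha = 1} special case with rate \eqn{1/b}.  The piecewise
#' baseline is constant at `rates[j]` on `(knots[j], knots[j+1]]`, with the
#' last rate extended beyond the final knot.
#'
#' @param family `"weibull"`, `"piecewise"` or `"exponential"`.
#' @param shape,scale Weibull shape/scale (both > 0); for `"exponential"`,
#'   `scale` = 1/rate and `shape` is fixed at 1.
#' @param rates positive piecewise rates, one per interval.
#' @param knots increasing knot vector starting at 0, length
#'   `length(rates) + 1`.
#' @param beta named log-hazard-ratio vector aligned to design columns.
#' @return object of class `idm_transition`.
#' @export
transition_params <- function(family = c("weibull", "piecewise", "exponential"),
                              shape = 1, scale = 1, rates = NULL, knots = NULL,
                              beta = numeric(0)) {
  family <- match.arg(family)
  if (family == "exponential") shape <- 1
  if (family %in% c("weibull", "exponential")) {
    stopifnot(shape > 0, scale > 0)
  } else {
    stopifnot(!is.null(rates), !is.null(knots),
              length(knots) == length(rates) + 1L,
              all(diff(knots) > 0), knots[1] == 0, all(rates >= 0))
  }
  stopifnot(all(is.finite(beta)))
  structure(list(family = family, shape = shape, scale = scale,
                 rates = rates, knots = knots, beta = beta),
            class = "idm_transition")
}

# baseline log-hazard at t > 0, vectorized
.base_loghaz <- function(tp, t) {
  if (tp$family == "piecewise") {
    j <- pmin(findInterval(t, tp$knots, left.open = TRUE,
                           rightmost.closed = FALSE),
              length(tp$rates))
    j[t <= 0] <- 1L  # caller guards t > 0
    log(tp$rates[pmax(j, 1L)])
  } else {
    log(tp$shape) - log(tp$scale) + (tp$shape - 1) * (log(t) - log(tp$scale))
  }
}

# baseline cumulative hazard at t >= 0, vectorized
.base_cumhaz <- function(tp, t) {
  if (tp$family == "piecewise") {
    J <- length(tp$rates)
    up <- c(tp$knots[-1][-J], Inf)  # last rate extends past the final knot
    if (J == 1) up <- Inf
    H <- numeric(length(t))
    for (j in seq_len(J)) {
      H <- H + tp$rates[j] * pmax(0, pmin(t, up[j]) - tp$knots[j])
    }
    H
  } else {
    exp(tp$shape * (log(pmax(t, 0)) - log(tp$scale))) * (t > 0)
  }
}

# inverse baseline cumulative hazard (for simulation by inversion)
.base_cumhaz_inv <- function(tp, H) {
  if (tp$family == "piecewise") {
    K <- tp$knots
    J <- length(tp$rates)
    cumK <- c(0, cumsum(tp$rates * diff(K)))  # cumulative hazard at each knot
    j <- pmax(1L, findInterval(H, cumK))      # last rate extends past K[J+1]
    r <- tp$rates[pmin(j, J)]
    K[pmin(j, J + 1L)] + (H - cumK[pmin(j, J + 1L)]) / r
  } else {
    tp$scale * H^(1 / tp$shape)
  }
}

.lp <- function(tp, x) {
  if (length(tp$beta) == 0) return(if (is.matrix(x)) numeric(nrow(x)) else 0)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(tp$beta))
    drop(x %*% tp$beta)
  } else {
    stopifnot(length(x) == length(tp$beta))
    sum(x * tp$beta)
  }
}

#' Transition hazard, cumulative hazard and survival
#'
#' `hazard()` evaluates \eqn{\lambda(t|x)} (per year) at times `t > 0`;
#' `cumulative_hazard()` evaluates \eqn{\Lambda(t|x)} at `t >= 0`; and
#' `survival_prob()` returns \eqn{\exp(-\Lambda(t|x))}.
#'
#' @param tp an [transition_params()] object.
#' @param t time(s) in years since entry into the origin state.
#' @param x design row (named vector) or matrix aligned to `tp$beta`; omit
#'   for the baseline.
#' @return numeric vector.
#' @export
hazard <- function(tp, t, x = NULL) {
  if (any(t <= 0)) stop("hazard is defined for t > 0")
  lp <- if (is.null(x)) 0 else .lp(tp, x)
  exp(.base_loghaz(tp, t) + lp)
}

#' @rdname hazard
#' @export
cumulative_hazard <- function(tp, t, x = NULL) {
  if (any(t < 0)) stop("cumulative hazard is defined for t >= 0")
  lp <- if (is.null(x)) 0 else .lp(tp, x)
  .base_cumhaz(tp, t) * exp(lp)
}

#' @rdname hazard
#' @export
survival_prob <- function(tp, t, x = NULL) {
  exp(-cumulative_hazard(tp, t, x))
}
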