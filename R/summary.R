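#' Posterior hazard-ratio table
#'
#' Summarizes the posterior draws of each transition's coefficients as
#' hazard ratios: posterior mean of `exp(draws)` with equal-tailed 2.5th and
#' 97.5th percentile credible limits.  When the fit includes
#' treatment-by-covariate interactions, per-arm hazard ratios are reported:
#' the surgery-arm HR from the main-effect column and the radiotherapy-arm
#' HR from the elementwise sum of the main-effect and interaction columns
#' before exponentiation.  Arbitrary linear contrasts of coefficients may be
#' requested explicitly.
#'
#' @param fit an `idm_fit` (or a draws matrix with `"t12:term"`-style
#'   column labels).
#' @param contrasts optional named list; each element is a named numeric
#'   vector of weights over draw columns, e.g.
#'   `list(rt_arm = c("t12:gleason_9_10" = 1, "t12:rt_x_gleason_9_10" = 1))`.
#' @param prob credible level (default 0.95, equal-tailed).
#' @return data frame with columns `transition`, `term`, `arm`, `hr`,
#'   `lower`, `upper`, `ess`; class `idm_hr_table`.
#' @export
summarize_posterior <- function(fit, contrasts = NULL, prob = 0.95) {
  draws <- if (inherits(fit, "idm_fit")) fit$draws else fit
  if (nrow(draws) < 100)
    stop("need at least 100 post-burn-in draws to summarize")
  a <- (1 - prob) / 2
  one <- function(v, transition, term, arm) {
    h <- exp(v)
    data.frame(transition = transition, term = term, arm = arm,
               hr = mean(h),
               lower = unname(stats::quantile(h, a)),
               upper = unname(stats::quantile(h, 1 - a)),
               ess = ess(v), stringsAsFactors = FALSE)
  }
  rows <- list()
  base_pat <- "(log_shape|log_scale|log_rate|log_h[0-9]+)$"
  for (cn in colnames(draws)) {
    parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
    tr <- parts[1]; term <- parts[2]
    if (grepl(base_pat, term) || startsWith(term, "rt_x_")) next
    has_int <- paste0(tr, ":rt_x_", term) %in% colnames(draws)
    if (has_int && term != "treatment_rt") {
      rows[[length(rows) + 1]] <- one(draws[, cn], tr, term, "surgery")
      rows[[length(rows) + 1]] <-
        one(draws[, cn] + draws[, paste0(tr, ":rt_x_", term)], tr, term,
            "radiotherapy")
    } else {
      rows[[length(rows) + 1]] <- one(draws[, cn], tr, term, "both")
    }
  }
  for (nm in names(contrasts)) {
    w <- contrasts[[nm]]
    bad <- setdiff(names(w), colnames(draws))
    if (length(bad)) stop("contrast references unknown label(s): ",
                          paste(bad, collapse = ", "))
    v <- drop(draws[, names(w), drop = FALSE] %*% w)
    rows[[length(rows) + 1]] <- one(v, "contrast", nm, "custom")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("idm_hr_table", "data.frame")
  out
}

#' @export
print.idm_hr_table <- function(x, digits = 2, ...) {
  y <- x
  y$hr <- round(y$hr, digits); y$lower <- round(y$lower, digits)
  y$upper <- round(y$upper, digits); y$ess <- round(y$ess)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.idm_fit <- function(x, ...) {
  cat("Bayesian illness-death model fit\n")
  cat(sprintf("  %d patients; events: CF %d, death w/o CF %d, death after CF %d\n",
              x$n, x$events[["t12"]], x$events[["t13"]], x$events[["t23"]]))
  cat(sprintf("  %d retained draws (%d iterations, burn-in %d, thin %d), seed %d\n",
              nrow(x$draws), x$control$iters, x$control$burn_in,
              x$control$thin, x$seed))
  cat(sprintf("  acceptance: median %.2f (range %.2f-%.2f); min ESS %.0f; max split-Rhat %.3f\n",
              stats::median(x$accept), min(x$accept), max(x$accept),
              min(x$ess), max(x$rhat, na.rm = TRUE)))
  if (length(x$imputation$fields))
    cat("  imputed fields:",
        paste(sprintf("%s (%d)", x$imputation$fields,
                      x$imputation$n_missing), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.idm_fit <- function(object, ...) summarize_posterior(object, ...)

#' @export
coef.idm_fit <- function(object, ...) {
  keep <- !grepl("(log_shape|log_scale|log_rate|log_h[0-9]+)$",
                 colnames(object$draws))
  colMeans(object$draws[, keep, drop = FALSE])
}

#' Forest plot / trace plot of a fitted model
#'
#' @param x an `idm_fit`.
#' @param type `"forest"` (posterior HRs with 95% CrI per transition) or
#'   `"trace"` (chain traces for selected parameters).
#' @param pars for `type = "trace"`, column labels to plot (default: the
#'   treatment coefficients).
#' @param ... ignored.
#' @export
plot.idm_fit <- function(x, type = c("forest", "trace"), pars = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (is.null(pars))
      pars <- grep(":treatment_rt$", colnames(x$draws), value = TRUE)
    op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op))
    for (p in pars)
      graphics::plot(x$draws[, p], type = "l", ylab = p, xlab = "")
    return(invisible(x))
  }
  tab <- summarize_posterior(x)
  tab <- tab[order(tab$transition, tab$term), ]
  k <- nrow(tab)
  op <- graphics::par(mar = c(4, 11, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$hr, k:1, log = "x", pch = 16,
                 xlim = range(c(tab$lower, tab$upper)),
                 yaxt = "n", xlab = "Hazard ratio", ylab = "")
  graphics::segments(tab$lower, k:1, tab$upper, k:1)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  lab <- paste(tab$transition, tab$term,
               ifelse(tab$arm %in% c("both", "custom"), "", tab$arm))
  graphics::axis(2, at = k:1, labels = lab, las = 1, cex.axis = 0.6)
  invisible(x)
}
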