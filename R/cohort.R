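#' Read a patient-level cohort from CSV
#'
#' One row per patient.  Required columns: `id`, `age`, `gland_volume`,
#' `psa`, `cci` (0/1/2/3+), `gleason` (5/6, 7=3+4, 7=4+3, 8, 9/10), `pni`
#' (0/1), `ct` (1/2/3), `race` (White/AfricanAmerican/Other), `tx_year`
#' (1996-2000/2001-2006/2007-2013), `treatment` (surgery/radiotherapy),
#' `cf_time`, `cf_event`, `death_time`, `death_event`.  Missing covariate
#' values are encoded as an empty field or the token `NA`; `treatment`,
#' `tx_year`, `age` and the outcome columns must never be missing.
#'
#' Times are years since treatment, administratively censored at 15.
#'
#' @param path CSV file path.
#' @return validated cohort `data.frame` (class `idm_cohort`).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = TRUE)
  validate_cohort(df)
}

#' Write a cohort to CSV (missing written as empty)
#' @param cohort cohort data frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

.cohort_cols <- c("id", "age", "gland_volume", "psa", "cci", "gleason", "pni",
                  "ct", "race", "tx_year", "treatment", "cf_time", "cf_event",
                  "death_time", "death_event")

#' Validate a cohort against the data-model invariants
#'
#' Checks column presence, categorical levels, never-missing fields, and the
#' ordering invariants `cf_time <= death_time`, all times in `[0, 15]`,
#' events implying positive times.  Rows violating an invariant are reported
#' with their row number and id.
#'
#' @param df a data frame.
#' @return the validated data frame, with categoricals as factors, class
#'   `idm_cohort` prepended.
#' @export
validate_cohort <- function(df) {
  miss <- setdiff(.cohort_cols, names(df))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, .cohort_cols]
  df$id <- as.character(df$id)
  for (f in names(.idm_levels)) {
    v <- as.character(df[[f]])
    bad <- which(!is.na(v) & !v %in% .idm_levels[[f]])
    if (length(bad))
      stop(sprintf("row %d (id %s): invalid %s value '%s'",
                   bad[1], df$id[bad[1]], f, v[bad[1]]))
    df[[f]] <- factor(v, levels = .idm_levels[[f]])
  }
  for (f in c("age", "gland_volume", "psa", "pni", "cf_time", "cf_event",
              "death_time", "death_event")) {
    df[[f]] <- as.numeric(df[[f]])
  }
  for (f in c("age", "treatment", "tx_year", "cf_time", "cf_event",
              "death_time", "death_event")) {
    if (anyNA(df[[f]])) {
      i <- which(is.na(df[[f]]))[1]
      stop(sprintf("row %d (id %s): '%s' must never be missing", i, df$id[i], f))
    }
  }
  chk <- function(bad, msg) {
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("row %d (id %s): %s", i, df$id[i], msg))
    }
  }
  chk(df$cf_time > df$death_time, "cf_time exceeds death_time")
  chk(df$cf_time < 0 | df$death_time < 0, "negative event time")
  chk(df$cf_time > 15 | df$death_time > 15,
      "event time exceeds the 15-year administrative horizon")
  chk(!df$cf_event %in% c(0, 1) | !df$death_event %in% c(0, 1),
      "event indicators must be 0/1")
  chk(df$cf_event == 1 & df$cf_time <= 0, "CF event at time <= 0")
  chk(df$death_event == 1 & df$death_time <= 0, "death event at time <= 0")
  chk(!is.na(df$pni) & !df$pni %in% c(0, 1), "pni must be 0/1")
  chk(!is.na(df$psa) & df$psa <= 0, "psa must be positive")
  chk(!is.na(df$gland_volume) & df$gland_volume <= 0, "gland_volume must be positive")
  class(df) <- c("idm_cohort", "data.frame")
  df
}

#' Percentage as printed in a descriptive table
#'
#' `100 * num / den`, rounded to one decimal -- the convention of the
#' cohort's descriptive table, where percentages are computed within the
#' treatment arm on that row's stated denominator.
#'
#' @param num numerator count(s).
#' @param den denominator count(s).
#' @return numeric percentage(s), one decimal.
#' @export
pct <- function(num, den) round(100 * num / den, 1)

#' Pooled mean and SD across groups
#'
#' Combines per-group means and SDs into the overall mean and SD (the SD via
#' the standard within/between decomposition with the n-1 convention).
#'
#' @param means group means.
#' @param sds group SDs (may be `NULL` if only the mean is needed).
#' @param ns group sizes.
#' @return list with `mean`, `sd` (NA if `sds` is NULL), `n`.
#' @export
pooled_stats <- function(means, sds = NULL, ns) {
  n <- sum(ns)
  m <- sum(means * ns) / n
  s <- NA_real_
  if (!is.null(sds)) {
    ssq <- sum((ns - 1) * sds^2) + sum(ns * (means - m)^2)
    s <- sqrt(ssq / (n - 1))
  }
  list(mean = m, sd = s, n = n)
}

#' Arm-wise descriptive summary of a cohort
#'
#' Produces the descriptive statistics table: per-arm counts and percentages
#' for each categorical level (on the arm's denominator), mean (SD)
#' for continuous covariates, missing counts, outcome event counts, and the
#' pooled mean/SD of age across arms.
#'
#' @param cohort cohort data frame.
#' @return list with `continuous`, `categorical`, `outcomes` data frames and
#'   `pooled_age` (list mean/sd/n); class `idm_cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  arms <- .idm_levels$treatment
  by_arm <- lapply(arms, function(a) cohort[cohort$treatment == a, , drop = FALSE])
  names(by_arm) <- arms
  narm <- vapply(by_arm, nrow, 0L)

  cont <- do.call(rbind, lapply(c("age", "gland_volume", "psa"), function(f) {
    do.call(rbind, lapply(arms, function(a) {
      x <- by_arm[[a]][[f]]
      data.frame(variable = f, arm = a, n = length(x),
                 mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE),
                 n_missing = sum(is.na(x)),
                 pct_missing = pct(sum(is.na(x)), length(x)))
    }))
  }))

  cat_fields <- c("cci", "gleason", "pni", "ct", "race", "tx_year")
  cats <- do.call(rbind, lapply(cat_fields, function(f) {
    do.call(rbind, lapply(arms, function(a) {
      x <- by_arm[[a]][[f]]
      den <- length(x)
      lev <- if (f == "pni") "1" else .idm_levels[[f]]
      cnt <- if (f == "pni") sum(x == 1, na.rm = TRUE) else
        as.integer(table(factor(x, levels = lev)))
      data.frame(variable = f, arm = a, level = lev, n = cnt,
                 pct = pct(cnt, den),
                 n_missing = sum(is.na(x)),
                 pct_missing = pct(sum(is.na(x)), den))
    }))
  }))

  outc <- do.call(rbind, lapply(arms, function(a) {
    d <- by_arm[[a]]
    data.frame(arm = a, n = nrow(d),
               cf = sum(d$cf_event), cf_pct = pct(sum(d$cf_event), nrow(d)),
               death = sum(d$death_event),
               death_pct = pct(sum(d$death_event), nrow(d)),
               death_after_cf = sum(d$cf_event & d$death_event),
               death_after_cf_pct = pct(sum(d$cf_event & d$death_event), nrow(d)),
               median_followup = stats::median(d$death_time))
  }))

  age_by <- lapply(by_arm, function(d) c(mean(d$age), stats::sd(d$age), nrow(d)))
  keep <- narm > 0
  pooled_age <- pooled_stats(
    means = vapply(age_by[keep], `[`, 0, 1),
    sds = vapply(age_by[keep], `[`, 0, 2),
    ns = vapply(age_by[keep], `[`, 0, 3))

  structure(list(continuous = cont, categorical = cats, outcomes = outc,
                 pooled_age = pooled_age),
            class = "idm_cohort_summary")
}

#' @export
print.idm_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (surgery %d, radiotherapy %d)\n",
              sum(x$outcomes$n), x$outcomes$n[1], x$outcomes$n[2]))
  cat(sprintf("Pooled age: mean %.1f (SD %.1f)\n",
              x$pooled_age$mean, x$pooled_age$sd))
  cat("\nOutcomes by arm:\n")
  print(x$outcomes, row.names = FALSE, digits = 3)
  cat("\nContinuous covariates:\n")
  print(x$continuous, row.names = FALSE, digits = 3)
  invisible(x)
}
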