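#' Model specification for the illness-death model
#'
#' Defines, per transition, which covariates enter the linear predictor, how
#' continuous covariates are transformed (age centered and divided by 10,
#' log-PSA and log-volume standardized, time-to-CF divided by 15 on the
#' CF-to-death transition), the reference level of each categorical, the
#' baseline-hazard family, and whether treatment-by-covariate interactions
#' are included.
#'
#' Centering constants may be supplied explicitly; any left `NULL` are
#' computed from the cohort when the model is fitted (or when
#' [freeze_centering()] is called) and are then frozen into the returned
#' specification so that prediction reuses them verbatim.
#'
#' @param terms named list with elements `t12`, `t13`, `t23`: character
#'   vectors of term names.  Available terms: `"treatment"`, `"age"`,
#'   `"log_psa"`, `"log_volume"`, `"cci"`, `"gleason"`, `"gleason_grp"`
#'   (Gleason grouped to <=7 / 8 / 9-10, for the sparse CF-to-death
#'   transition), `"pni"`, `"ct"`, `"race"`, `"tx_year"`, and (t23 only)
#'   `"cf_time"`.
#' @param interactions logical; include treatment-by-covariate interaction
#'   columns for every non-treatment term.
#' @param baseline named list `t12`/`t13`/`t23`, each one of `"weibull"`,
#'   `"piecewise"`, `"exponential"`.
#' @param knots for piecewise baselines, a named list of knot vectors
#'   (interior knots on (0, 15)); `NULL` means quintiles of that
#'   transition's event times, chosen at fit time.
#' @param centering list with `age_center` (years), `log_psa` (mean, sd),
#'   `log_volume` (mean, sd); `NULL` entries are filled from data.
#' @param epsilon sojourn time (years) substituted when CF and death are
#'   recorded on the same day; default 1/365.
#' @return an object of class `idm_spec`.
#' @export
idm_spec <- function(terms = NULL,
                     interactions = FALSE,
                     baseline = list(t12 = "weibull", t13 = "weibull", t23 = "weibull"),
                     knots = NULL,
                     centering = list(age_center = NULL, log_psa = NULL, log_volume = NULL),
                     epsilon = 1 / 365) {
  if (is.null(terms)) {
    full <- c("treatment", "age", "log_psa", "log_volume", "cci", "gleason",
              "pni", "ct", "race", "tx_year")
    terms <- list(t12 = full, t13 = full,
                  t23 = c("treatment", "age", "log_psa", "gleason_grp", "cf_time"))
  }
  stopifnot(all(c("t12", "t13", "t23") %in% names(terms)))
  for (tr in c("t12", "t13")) {
    if ("cf_time" %in% terms[[tr]])
      stop("'cf_time' is only available on transition 2->3")
  }
  baseline <- lapply(baseline, match.arg,
                     choices = c("weibull", "piecewise", "exponential"))
  structure(list(terms = terms, interactions = isTRUE(interactions),
                 baseline = baseline, knots = knots,
                 centering = centering, epsilon = epsilon),
            class = "idm_spec")
}

#' @export
print.idm_spec <- function(x, ...) {
  cat("Illness-death model specification\n")
  for (tr in c("t12", "t13", "t23")) {
    cat(sprintf("  %s [%s]: %s\n", sub("t", "", tr), x$baseline[[tr]],
                paste(x$terms[[tr]], collapse = ", ")))
  }
  cat(sprintf("  interactions: %s\n", x$interactions))
  ctr <- x$centering
  if (!is.null(ctr$age_center))
    cat(sprintf("  centering: age %.2f; log-PSA (%.3f, %.3f); log-volume (%.3f, %.3f)\n",
                ctr$age_center, ctr$log_psa[1], ctr$log_psa[2],
                ctr$log_volume[1], ctr$log_volume[2]))
  invisible(x)
}

# factor levels used throughout; reference level first
.idm_levels <- list(
  cci       = c("0", "1", "2", "3+"),
  gleason   = c("5/6", "7=3+4", "7=4+3", "8", "9/10"),
  ct        = c("1", "2", "3"),
  race      = c("White", "AfricanAmerican", "Other"),
  tx_year   = c("1996-2000", "2001-2006", "2007-2013"),
  treatment = c("surgery", "radiotherapy")
)

# raw cohort fields needed by a term
.term_fields <- function(term) {
  switch(term,
         treatment = "treatment", age = "age", log_psa = "psa",
         log_volume = "gland_volume", cci = "cci", gleason = "gleason",
         gleason_grp = "gleason", pni = "pni", ct = "ct", race = "race",
         tx_year = "tx_year", cf_time = "cf_time",
         stop("unknown term: ", term))
}

#' Freeze centering constants from a cohort
#'
#' Fills any `NULL` centering constants of an [idm_spec()] with values
#' computed from the cohort: the mean age, and the mean/SD of log-PSA and
#' log-gland-volume over their observed values.  Natural logarithms are used.
#'
#' @param spec an `idm_spec`.
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @return the spec with all centering constants set.
#' @export
freeze_centering <- function(spec, cohort) {
  ctr <- spec$centering
  if (is.null(ctr$age_center)) ctr$age_center <- mean(cohort$age)
  if (is.null(ctr$log_psa)) {
    lp <- log(cohort$psa[!is.na(cohort$psa)])
    ctr$log_psa <- c(mean(lp), stats::sd(lp))
  }
  if (is.null(ctr$log_volume)) {
    lv <- log(cohort$gland_volume[!is.na(cohort$gland_volume)])
    ctr$log_volume <- c(mean(lv), stats::sd(lv))
  }
  if (any(!is.finite(c(ctr$age_center, ctr$log_psa, ctr$log_volume))))
    stop("non-finite centering constants; check psa / gland_volume values")
  spec$centering <- ctr
  spec
}

# columns (matrix with labels) contributed by one term, vectorized over rows
.term_cols <- function(df, term, ctr) {
  n <- nrow(df)
  dummy <- function(f, levels, labels) {
    f <- factor(as.character(f), levels = levels)
    m <- matrix(0, n, length(levels) - 1L, dimnames = list(NULL, labels))
    for (j in seq_along(labels)) m[, j] <- as.numeric(f == levels[j + 1L])
    m
  }
  switch(term,
    treatment = matrix(as.numeric(df$treatment == "radiotherapy"),
                       dimnames = list(NULL, "treatment_rt"), ncol = 1),
    age = matrix((df$age - ctr$age_center) / 10,
                 dimnames = list(NULL, "age10"), ncol = 1),
    log_psa = matrix((log(df$psa) - ctr$log_psa[1]) / ctr$log_psa[2],
                     dimnames = list(NULL, "log_psa_std"), ncol = 1),
    log_volume = matrix((log(df$gland_volume) - ctr$log_volume[1]) / ctr$log_volume[2],
                        dimnames = list(NULL, "log_volume_std"), ncol = 1),
    cci = dummy(df$cci, .idm_levels$cci, c("cci_1", "cci_2", "cci_3plus")),
    gleason = dummy(df$gleason, .idm_levels$gleason,
                    c("gleason_7_34", "gleason_7_43", "gleason_8", "gleason_9_10")),
    gleason_grp = {
      g <- as.character(df$gleason)
      m <- cbind(gleason_8 = as.numeric(g == "8"),
                 gleason_9_10 = as.numeric(g == "9/10"))
      m[is.na(g), ] <- NA_real_
      m
    },
    pni = matrix(as.numeric(df$pni), dimnames = list(NULL, "pni"), ncol = 1),
    ct = dummy(df$ct, .idm_levels$ct, c("ct_2", "ct_3")),
    race = dummy(df$race, .idm_levels$race, c("race_aa", "race_other")),
    tx_year = dummy(df$tx_year, .idm_levels$tx_year,
                    c("txyear_2001_2006", "txyear_2007_2013")),
    cf_time = matrix(df$cf_time / 15, dimnames = list(NULL, "cftime15"), ncol = 1),
    stop("unknown term: ", term))
}

#' Build the design matrix for one transition
#'
#' Expands a cohort into the numeric design matrix of one transition's
#' proportional-hazards linear predictor: continuous covariates transformed
#' per the spec, categoricals reference-coded, and (optionally)
#' treatment-by-covariate interaction columns appended.  Missing values among
#' required covariates are an error -- imputation happens upstream.
#'
#' @param cohort cohort data frame.
#' @param spec an [idm_spec()] with frozen centering constants.
#' @param transition one of `"t12"`, `"t13"`, `"t23"` (aliases `"1->2"` etc.
#'   accepted).
#' @return numeric matrix with one row per cohort row and labelled columns.
#' @export
design_matrix <- function(cohort, spec, transition) {
  transition <- .norm_transition(transition)
  if (is.null(spec$centering$age_center))
    stop("centering constants not frozen; call freeze_centering() first")
  terms <- spec$terms[[transition]]
  need <- unique(vapply(terms, .term_fields, ""))
  for (f in need) {
    if (anyNA(cohort[[f]]))
      stop(sprintf("missing values in '%s' for transition %s; impute before encoding",
                   f, transition))
  }
  # NA dummy for unseen level would silently zero; check levels explicitly
  for (f in intersect(need, names(.idm_levels))) {
    bad <- !as.character(cohort[[f]]) %in% .idm_levels[[f]]
    if (any(bad))
      stop(sprintf("invalid level(s) in '%s': %s", f,
                   paste(unique(as.character(cohort[[f]])[bad]), collapse = ", ")))
  }
  if (length(terms) == 0) return(matrix(numeric(0), nrow(cohort), 0))
  cols <- lapply(terms, .term_cols, df = cohort, ctr = spec$centering)
  X <- do.call(cbind, cols)
  if (spec$interactions) {
    trt <- X[, "treatment_rt"]
    main <- setdiff(colnames(X), "treatment_rt")
    XI <- X[, main, drop = FALSE] * trt
    colnames(XI) <- paste0("rt_x_", main)
    X <- cbind(X, XI)
  }
  X
}

#' Encode a single patient record as a design row
#'
#' @param record a one-row cohort data frame (a `PatientRecord`).
#' @inheritParams design_matrix
#' @return named numeric vector.
#' @export
encode_design_row <- function(record, spec, transition) {
  stopifnot(nrow(record) == 1L)
  drop(design_matrix(record, spec, transition)[1L, ])
}

.norm_transition <- function(transition) {
  map <- c("t12" = "t12", "t13" = "t13", "t23" = "t23",
           "1->2" = "t12", "1->3" = "t13", "2->3" = "t23",
           "12" = "t12", "13" = "t13", "23" = "t23")
  out <- map[as.character(transition)]
  if (is.na(out)) stop("unknown transition: ", transition)
  unname(out)
}
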