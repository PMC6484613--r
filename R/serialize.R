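# On-disk representations: the model specification as JSON or YAML,
# transition parameters as JSON, and fitted draws as labelled CSV with a
# JSON metadata sidecar.

#' Write / read a model specification
#'
#' The specification (terms, interactions, baseline families, knots,
#' centering constants, epsilon) round-trips through JSON or YAML, chosen
#' by file extension.
#'
#' @param spec an [idm_spec()].
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return `write_spec` returns the path invisibly; `read_spec` the spec.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "idm_spec"))
  x <- unclass(spec)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path, precision = 15)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  ctr <- x$centering
  if (!is.null(ctr)) ctr <- lapply(ctr, function(v) if (is.null(v)) NULL else as.numeric(v))
  idm_spec(terms = lapply(x$terms, as.character),
           interactions = isTRUE(x$interactions),
           baseline = as.list(x$baseline),
           knots = if (length(x$knots)) lapply(x$knots, as.numeric) else NULL,
           centering = ctr %||% list(age_center = NULL, log_psa = NULL,
                                     log_volume = NULL),
           epsilon = as.numeric(x$epsilon))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read transition parameters as JSON
#'
#' @param params a single [transition_params()] or a named list of them
#'   (e.g. a generator truth or the posterior-mean parameters of a fit).
#' @param path JSON file path.
#' @return `write_params` the path invisibly; `read_params` the object.
#' @export
write_params <- function(params, path) {
  ser <- function(tp) {
    stopifnot(inherits(tp, "idm_transition"))
    list(family = tp$family, shape = tp$shape, scale = tp$scale,
         rates = tp$rates, knots = tp$knots,
         beta = as.list(tp$beta))
  }
  x <- if (inherits(params, "idm_transition")) ser(params) else lapply(params, ser)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(y) {
    transition_params(y$family,
                      shape = y$shape %||% 1, scale = y$scale %||% 1,
                      rates = if (length(y$rates)) as.numeric(y$rates) else NULL,
                      knots = if (length(y$knots)) as.numeric(y$knots) else NULL,
                      beta = unlist(y$beta) %||% numeric(0))
  }
  if (!is.null(x$family)) de(x) else lapply(x, de)
}

#' Persist a fitted model's draws and metadata
#'
#' Writes `draws.csv` (labelled draw matrix) and `fit_meta.json` (seed,
#' chain settings, event counts, acceptance/ESS/Rhat summaries, imputation
#' info) into a directory.
#'
#' @param fit an `idm_fit`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "idm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$draws),
                   file.path(dir, "draws.csv"), row.names = FALSE)
  meta <- list(seed = fit$seed, n = fit$n, events = as.list(fit$events),
               iters = fit$control$iters, burn_in = fit$control$burn_in,
               thin = fit$control$thin,
               accept = as.list(round(fit$accept, 4)),
               ess = as.list(round(fit$ess, 1)),
               rhat = as.list(round(fit$rhat, 4)),
               imputed_fields = as.list(fit$imputation$n_missing))
  jsonlite::write_json(meta, file.path(dir, "fit_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
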