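#' Serialize models and fits to structured text (JSON)
#'
#' Models, fits, and study summaries are written as plain-text JSON so
#' that runs are portable and diffable. `write_pca_model()` /
#' `read_pca_model()` round-trip a [fit_pca()] model;
#' `write_fit()` serializes any `unmix_fit` (weights, diagnostics, cost
#' trace, residual); `write_study()` writes a study's records and
#' summaries as CSV next to a JSON manifest.
#'
#' @param model A `pca_model`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  obj <- list(
    type = "pca_model",
    axis = model$axis,
    mean = model$mean,
    components = apply(model$components, 1, identity, simplify = FALSE),
    eigenvalues = model$eigenvalues,
    n_samples = model$n_samples,
    n_requested = model$n_requested,
    truncated = model$truncated
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "pca_model")) {
    stop_validation(sprintf("'%s' is not a serialized PCA model.", path))
  }
  comps <- if (length(obj$eigenvalues)) {
    # stored row-per-component; simplification may yield a matrix or a
    # list of rows depending on the reader
    if (is.matrix(obj$components)) {
      unname(obj$components)
    } else {
      matrix(unlist(obj$components), nrow = length(obj$eigenvalues),
             byrow = TRUE)
    }
  } else {
    matrix(0, 0, length(obj$mean))
  }
  structure(list(
    axis = as.numeric(obj$axis), mean = as.numeric(obj$mean),
    components = comps, eigenvalues = as.numeric(obj$eigenvalues),
    n_samples = as.integer(obj$n_samples),
    n_requested = as.integer(obj$n_requested),
    truncated = isTRUE(obj$truncated)
  ), class = "pca_model")
}

#' @rdname write_pca_model
#' @param fit An `unmix_fit`.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    type = "unmix_fit",
    method = fit$method,
    weights = as.list(fit$weights),
    concentration = fit$concentration %||% NULL,
    diagnostics = fit$diagnostics,
    iterations = fit$iterations %||% NULL,
    converged = fit$converged %||% NULL,
    cost_trace = fit$cost_trace %||% NULL,
    axis = fit$axis,
    fitted = fit$fitted,
    residual = fit$residual
  )
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_model
#' @param study A `study_result`.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$records, file.path(dir, "records.csv"))
  readr::write_csv(study$summaries, file.path(dir, "summaries.csv"))
  readr::write_csv(dw_histogram(study$records),
                   file.path(dir, "dw_histogram.csv"))
  jsonlite::write_json(list(
    type = "study_result",
    n_combinations = study$n_combinations,
    n_records = nrow(study$records),
    methods = unique(study$records$method),
    weight_levels = study$config$weight_levels,
    ref_concentration = study$config$ref_concentration,
    seed = study$config$seed
  ), file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
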