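#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PCA variability model
#'
#' @param x A [fit_pca()] model.
#' @param ... Unused.
#' @return One row per component: `component`, `eigenvalue`,
#'   `variance_fraction`.
#' @export
tidy.pca_model <- function(x, ...) {
  p <- length(x$eigenvalues)
  tibble(
    component = seq_len(p),
    eigenvalue = x$eigenvalues,
    variance_fraction = if (p) x$eigenvalues / sum(x$eigenvalues) else
      numeric(0)
  )
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble(
    n_components = length(x$eigenvalues),
    n_requested = x$n_requested,
    n_samples = x$n_samples,
    n_points = length(x$mean),
    total_variance = sum(x$eigenvalues),
    truncated = x$truncated
  )
}

#' Tidy an unmixing fit
#'
#' @param x An `unmix_fit` (from [cls_fit()], [hla_estimate()] or
#'   [hlp_fit()]).
#' @param ... Unused.
#' @return One row per fitted reference weight: `term`, `estimate`.
#' @export
tidy.unmix_fit <- function(x, ...) {
  tibble(term = names(x$weights) %||%
           paste0("w", seq_along(x$weights)),
         estimate = unname(x$weights))
}

#' @rdname tidy.unmix_fit
#' @export
glance.unmix_fit <- function(x, ...) {
  tibble(
    method = x$method,
    durbin_watson = x$diagnostics$durbin_watson %||% NA_real_,
    rss = if (!is.null(x$residual)) sum(x$residual^2) else NA_real_,
    iterations = x$diagnostics$iterations %||% NA_integer_,
    converged = x$diagnostics$converged %||% NA
  )
}

#' Tidy a factorial study result
#'
#' @param x A [run_factorial_study()] result.
#' @param ... Unused.
#' @return The per-(method, weight level) summary tibble.
#' @export
tidy.study_result <- function(x, ...) x$summaries

#' @rdname tidy.study_result
#' @export
glance.study_result <- function(x, ...) {
  hlp <- dplyr::filter(x$records, .data$method == "HLP")
  tibble(
    n_combinations = x$n_combinations,
    n_records = nrow(x$records),
    n_methods = length(unique(x$records$method)),
    n_levels = length(x$config$weight_levels),
    hlp_convergence_rate = if (nrow(hlp)) mean(hlp$converged) else NA_real_
  )
}
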