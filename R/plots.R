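#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_errorbar geom_col labs facet_wrap scale_x_continuous
#'   scale_y_log10 position_dodge
#' @export
ggplot2::autoplot

#' Plot a spectral library
#'
#' All spectra as semi-transparent lines with the mean overlaid.
#'
#' @param object A [spectral_library()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_library <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(unclass(object),
                                                      check.names = FALSE)),
                              -"wavenumber",
                              names_to = "spectrum",
                              values_to = "intensity")
  mean_df <- tibble(wavenumber = library_axis(object),
                    intensity = colMeans(library_matrix(object)))
  ggplot(long, aes(.data$wavenumber, .data$intensity)) +
    geom_line(aes(group = .data$spectrum), alpha = 0.2) +
    geom_line(data = mean_df, colour = "firebrick", linewidth = 0.8) +
    labs(x = "wavenumber (cm⁻¹)", y = "intensity",
         title = sprintf("%d spectra (mean in red)", n_spectra(object)))
}

#' Plot a PCA variability model
#'
#' Mean spectrum and principal components in facets.
#'
#' @param object A [fit_pca()] model.
#' @param n_components How many components to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_model <- function(object, n_components = NULL, ...) {
  p <- nrow(object$components)
  show <- min(n_components %||% p, p)
  df <- dplyr::bind_rows(
    tibble(wavenumber = object$axis, value = object$mean,
           panel = "mean"),
    purrr::map_dfr(seq_len(show), function(i) {
      tibble(wavenumber = object$axis, value = object$components[i, ],
             panel = sprintf("PC%d (λ = %.3g)", i,
                             object$eigenvalues[i]))
    })
  )
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot(df, aes(.data$wavenumber, .data$value)) +
    geom_line() +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "wavenumber (cm⁻¹)", y = NULL)
}

#' Plot an unmixing fit
#'
#' Measured, fitted, and residual traces.
#'
#' @param object An `unmix_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.unmix_fit <- function(object, ...) {
  if (is.null(object$fitted)) {
    abort("this fit carries no fitted spectrum to plot.")
  }
  df <- dplyr::bind_rows(
    tibble(wavenumber = object$axis, value = object$measured,
           trace = "measured"),
    tibble(wavenumber = object$axis, value = object$fitted,
           trace = "fitted"),
    tibble(wavenumber = object$axis, value = object$residual,
           trace = "residual")
  )
  df$trace <- factor(df$trace, levels = c("measured", "fitted", "residual"))
  ggplot(df, aes(.data$wavenumber, .data$value, colour = .data$trace)) +
    geom_line() +
    labs(x = "wavenumber (cm⁻¹)", y = "intensity",
         title = sprintf("%s fit (Durbin-Watson %.3f)", object$method,
                         object$diagnostics$durbin_watson))
}

#' Plot a factorial study result
#'
#' Mean fractional error with +-1 sd error bars per method across the
#' weight ladder (log2 x-axis), the standard summary view of an
#' estimator-comparison study.
#'
#' @param object A [run_factorial_study()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_result <- function(object, ...) {
  s <- object$summaries
  ggplot(s, aes(log2(.data$true_weight), .data$mean_fractional_error,
                colour = .data$method)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_fractional_error -
                        .data$sd_fractional_error,
                      ymax = .data$mean_fractional_error +
                        .data$sd_fractional_error),
                  width = 0.2) +
    labs(x = "log2 true weight", y = "fractional error (mean ± sd)")
}

#' Plot per-method Durbin-Watson histograms
#'
#' @param records A data frame with `method` and `durbin_watson`
#'   columns (e.g. `study$records`).
#' @param bins Number of bins over \[0, 4\].
#' @return A ggplot of superimposed per-method histograms.
#' @export
plot_dw_histogram <- function(records, bins = 40) {
  h <- dw_histogram(records, bins)
  ggplot(h, aes(.data$bin_low + 2 / bins, .data$count,
                fill = .data$method)) +
    geom_col(position = "identity", alpha = 0.5) +
    labs(x = "Durbin-Watson statistic", y = "count")
}
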