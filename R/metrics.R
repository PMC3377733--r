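#' Durbin-Watson statistic of a residual vector
#'
#' Ratio of the summed squared successive differences of the residual
#' (ordered by ascending wavenumber) to its summed squares:
#' \deqn{DW = \sum_i (e_i - e_{i-1})^2 / \sum_i e_i^2.}
#' DW always lies in \[0, 4\]; 2 indicates no serial correlation between
#' successive residuals, values toward 0 positive serial correlation
#' (structured, poorly fit residuals), values toward 4 negative serial
#' correlation.
#'
#' @param residual Numeric vector of length >= 2, not all zero.
#' @return The statistic, a number in \[0, 4\].
#' @examples
#' durbin_watson(c(1, -1, 1, -1)) # 3
#' @export
durbin_watson <- function(residual) {
  residual <- as.numeric(residual)
  if (length(residual) < 2) {
    stop_validation("Durbin-Watson needs at least 2 residual values.")
  }
  denom <- sum(residual^2)
  if (denom == 0) {
    abort("Durbin-Watson is undefined for an all-zero residual.",
          class = "ramanmix_undefined_statistic_error")
  }
  sum(diff(residual)^2) / denom
}

#' Signed fractional error of a concentration estimate
#'
#' `(estimated - true) / true`. Signed, so over- and under-estimation
#' do not cancel silently in individual records; summaries report mean
#' and standard deviation per level.
#'
#' @param estimated Estimated concentration(s).
#' @param true True concentration(s), nonzero.
#' @return Signed fractional error(s).
#' @examples
#' fractional_error(0.4, 0.8) # -0.5
#' @export
fractional_error <- function(estimated, true) {
  if (any(true == 0)) {
    abort("fractional error is undefined for a true concentration of 0.",
          class = "ramanmix_undefined_metric_error")
  }
  (estimated - true) / true
}

#' Histogram of Durbin-Watson statistics per method
#'
#' Bins each method's DW values over \[0, 4\] with shared bin edges, the
#' tabular analogue of superimposed method histograms.
#'
#' @param records A data frame with columns `method` and
#'   `durbin_watson` (e.g. the `records` of [run_factorial_study()]).
#' @param bins Number of equal-width bins over \[0, 4\].
#' @return A tibble with columns `method`, `bin_low`, `bin_high`,
#'   `count`. The last bin is closed at 4; the others are half-open
#'   `[low, high)`.
#' @export
dw_histogram <- function(records, bins = 40) {
  stopifnot(is.data.frame(records),
            all(c("method", "durbin_watson") %in% names(records)))
  edges <- seq(0, 4, length.out = bins + 1)
  records |>
    dplyr::group_by(method = .data$method) |>
    dplyr::reframe({
      idx <- pmin(findInterval(.data$durbin_watson, edges,
                               rightmost.closed = TRUE), bins)
      tibble(
        bin_low = edges[seq_len(bins)],
        bin_high = edges[-1],
        count = tabulate(idx, nbins = bins)
      )
    })
}
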