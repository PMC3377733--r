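#' Configuration for the synthetic spectral-library generator
#'
#' The generator emulates the variability observed in calibration scans
#' of a Raman-enhanced nanoparticle solution and a paraffin-like
#' background: each spectrum is a sum of Gaussian peaks whose
#' amplitudes and centers jitter from sample to sample, plus a broad
#' baseline bump of variable amplitude (the dominant background
#' variation mode near 1600-1800 cm^-1), plus i.i.d. additive noise.
#'
#' Defaults describe the analyte-like material: eight narrow peaks with
#' mild jitter (nanoparticle signatures are comparatively stable).
#' [background_generator_config()] gives the background-like
#' counterpart: fewer, broader peaks, stronger jitter, and the variable
#' broad bump.
#'
#' @param axis_range Wavenumber range, cm^-1 (default 400-1800).
#' @param n_points Number of axis samples L (default 700).
#' @param peaks Data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sd, cm^-1), `amplitude`.
#' @param amplitude_jitter Relative sd of per-peak amplitude variation.
#' @param shift_jitter Sd of per-peak center shifts, cm^-1.
#' @param baseline Either `NULL` or a list with `center`, `width`,
#'   `amplitude`, `amplitude_sd`: a broad Gaussian bump whose amplitude
#'   is drawn per spectrum.
#' @param noise_sigma Sd of i.i.d. additive Gaussian noise.
#' @param n_spectra Number of spectra to generate.
#' @param seed Integer seed; the library is fully determined by it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(axis_range = c(400, 1800),
                             n_points = 700,
                             peaks = NULL,
                             amplitude_jitter = 0.03,
                             shift_jitter = 0.5,
                             baseline = NULL,
                             noise_sigma = 0.02,
                             n_spectra = 50,
                             seed = 1L) {
  peaks <- peaks %||% data.frame(
    center    = c(520, 620, 730, 850, 1005, 1210, 1340, 1525),
    width     = c(10, 8, 12, 9, 8, 14, 12, 18),
    amplitude = c(0.55, 0.35, 0.8, 0.45, 1.0, 0.6, 0.9, 0.5)
  )
  stopifnot(all(c("center", "width", "amplitude") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop_config("peak widths must be > 0.")
  if (amplitude_jitter < 0 || shift_jitter < 0 || noise_sigma < 0) {
    stop_config("jitter and noise standard deviations must be >= 0.")
  }
  if (n_spectra < 1) stop_config("`n_spectra` must be >= 1.")
  if (!is.null(baseline)) {
    stopifnot(all(c("center", "width", "amplitude", "amplitude_sd") %in%
                    names(baseline)))
    if (baseline$width <= 0 || baseline$amplitude_sd < 0) {
      stop_config("invalid baseline bump parameters.")
    }
  }
  structure(list(
    axis_range = as.numeric(axis_range), n_points = as.integer(n_points),
    peaks = peaks, amplitude_jitter = amplitude_jitter,
    shift_jitter = shift_jitter, baseline = baseline,
    noise_sigma = noise_sigma, n_spectra = as.integer(n_spectra),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @rdname generator_config
#' @param ... Overrides passed on to [generator_config()].
#' @export
background_generator_config <- function(..., seed = 2L) {
  defaults <- list(
    peaks = data.frame(
      center    = c(650, 890, 1130, 1295, 1440),
      width     = c(45, 35, 55, 30, 60),
      amplitude = c(0.6, 0.8, 0.7, 1.0, 0.9)
    ),
    amplitude_jitter = 0.10,
    shift_jitter = 2,
    baseline = list(center = 1700, width = 90, amplitude = 1.0,
                    amplitude_sd = 0.4),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

#' Generate a synthetic spectral library
#'
#' Draws `n_spectra` spectra from the generative model described in
#' [generator_config()]: per spectrum, each peak's amplitude is scaled
#' by `1 + N(0, amplitude_jitter)` and its center shifted by
#' `N(0, shift_jitter)`; the baseline bump amplitude is drawn as
#' `N(amplitude, amplitude_sd)`; i.i.d. `N(0, noise_sigma)` noise is
#' added at every axis point. Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A [spectral_library()] with `config$n_spectra` spectra.
#' @examples
#' lib <- generate_library(generator_config(n_spectra = 5, seed = 7))
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  axis <- seq(config$axis_range[1], config$axis_range[2],
              length.out = config$n_points)
  n <- config$n_spectra
  np <- nrow(config$peaks)
  rows <- with_local_seed(config$seed, {
    out <- matrix(0, n, config$n_points)
    for (i in seq_len(n)) {
      amp <- config$peaks$amplitude *
        (1 + stats::rnorm(np, 0, config$amplitude_jitter))
      cen <- config$peaks$center + stats::rnorm(np, 0, config$shift_jitter)
      y <- numeric(config$n_points)
      for (p in seq_len(np)) {
        y <- y + amp[p] * exp(-(axis - cen[p])^2 /
                                (2 * config$peaks$width[p]^2))
      }
      if (!is.null(config$baseline)) {
        b <- config$baseline
        bamp <- stats::rnorm(1, b$amplitude, b$amplitude_sd)
        y <- y + bamp * exp(-(axis - b$center)^2 / (2 * b$width^2))
      }
      y <- y + stats::rnorm(config$n_points, 0, config$noise_sigma)
      out[i, ] <- y
    }
    out
  })
  spectral_library(axis, rows)
}

# evaluate expr under a fixed seed, restoring the caller's RNG state after
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
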