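#' Build a hybrid linear analysis calibration vector
#'
#' HLA estimates an analyte's concentration with a single dot product.
#' The calibration vector is the analyte reference spectrum with its
#' projections onto each background principal component removed
#' (so background variability within that span cannot bias the
#' estimate), then normalized so that `b . S_A = 1`: the dot product of
#' `b` with a measurement then reads out concentration in units of the
#' reference. Because the removed part lies in the component span,
#' `r . S_A = r . r` and this normalization equals `r / (r . r)`.
#'
#' @param background A [fit_pca()] model of the background calibration
#'   set (its mean is subtracted at estimation time).
#' @param analyte_ref The analyte reference spectrum `S_A`, measured at
#'   the reference concentration, on the background model's axis.
#' @return An object of class `hla_calibration`: `b` (length L),
#'   `axis`, `background_mean`, `n_components`, `residual_norm`
#'   (`||r||`), `analyte_overlap` (`r . S_A`).
#' @export
hla_calibrate <- function(background, analyte_ref) {
  s_a <- spectrum_values(analyte_ref, length(background$mean))
  r <- s_a
  if (nrow(background$components) > 0) {
    proj <- drop(background$components %*% s_a)
    r <- s_a - drop(crossprod(background$components, proj))
  }
  overlap <- sum(r * s_a)
  if (overlap <= 1e-12 * sum(s_a^2)) {
    abort(paste0(
      "analyte reference lies (numerically) inside the background ",
      "component span; HLA calibration is degenerate."),
      class = "ramanmix_degeneracy_error")
  }
  structure(list(
    b = r / overlap,
    axis = background$axis,
    background_mean = background$mean,
    n_components = nrow(background$components),
    residual_norm = sqrt(sum(r^2)),
    analyte_overlap = overlap
  ), class = "hla_calibration")
}

#' Estimate an analyte weight and concentration by HLA
#'
#' Subtracts the mean background spectrum, then takes the dot product
#' with the calibration vector. Any background deviation lying in the
#' modeled principal-component span is annihilated by construction; the
#' mean itself must be removed explicitly because it is not an
#' analyte-free zero signal.
#'
#' @param measured A spectrum on the calibration axis (or numeric
#'   vector).
#' @param calib An [hla_calibrate()] object.
#' @param ref_concentration Concentration of the solution from which
#'   `S_A` was measured (e.g. nM). Default 1 returns the raw weight
#'   scale.
#' @param background_model Optional: the [fit_pca()] background model
#'   used for calibration. Supplying it together with `analyte_ref`
#'   enables the fitted/residual reconstruction and the Durbin-Watson
#'   diagnostic.
#' @param analyte_ref Optional: the analyte reference spectrum used for
#'   calibration (see `background_model`).
#' @return An object of class `hla_estimate` (also `unmix_fit`):
#'   `weight`, `concentration`, `fitted`, `residual`, `diagnostics`.
#'   The fitted spectrum is the HLA model-space reconstruction:
#'   mean background + weight * S_A-direction + the projection of the
#'   remaining residual onto the background component span; the
#'   Durbin-Watson diagnostic is computed from what is left.
#' @export
hla_estimate <- function(measured, calib, ref_concentration = 1,
                         background_model = NULL, analyte_ref = NULL) {
  m <- spectrum_values(measured, length(calib$b))
  centered <- m - calib$background_mean
  weight <- sum(calib$b * centered)
  fitted <- NULL
  residual <- NULL
  dw <- NA_real_
  if (!is.null(background_model) && !is.null(analyte_ref)) {
    s_a <- spectrum_values(analyte_ref, length(calib$b))
    rest <- centered - weight * s_a
    if (nrow(background_model$components) > 0) {
      coef <- drop(background_model$components %*% rest)
      rest <- rest - drop(crossprod(background_model$components, coef))
    }
    residual <- rest
    fitted <- m - residual
    dw <- if (any(residual != 0)) durbin_watson(residual) else NA_real_
  }
  structure(list(
    method = "HLA",
    weights = c(analyte = weight),
    weight = weight,
    concentration = weight * ref_concentration,
    fitted = fitted,
    residual = residual,
    measured = m,
    axis = calib$axis,
    diagnostics = list(durbin_watson = dw)
  ), class = c("hla_estimate", "unmix_fit"))
}
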