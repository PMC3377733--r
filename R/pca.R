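#' Fit a principal-component variability model to a calibration library
#'
#' Characterizes how one compound's spectrum varies across replicate
#' measurements: the mean spectrum, the orthonormal principal components
#' of the mean-centered replicates, and the eigenvalues, where eigenvalue
#' p equals the sample variance (denominator N-1) of the projections of
#' the centered spectra onto component p. These models drive both HLA
#' (background span) and HLP (eigenvalue-penalized flexing).
#'
#' Eigenvalues below `1e-12` times the largest are treated as zero and
#' their components dropped; if fewer than `n_components` survive, the
#' model is truncated to the numerical rank and flagged (`truncated`).
#' Component signs are fixed so each component's largest-magnitude
#' element is positive.
#'
#' @param lib A [spectral_library()] with N >= 2 spectra.
#' @param n_components Number of components requested,
#'   `1 <= n_components <= min(N - 1, L)`. Default 5: estimates in this
#'   family of problems are insensitive to the count once it exceeds
#'   three or four.
#' @return An object of class `pca_model`: list with `axis`, `mean`
#'   (length L), `components` (P x L, orthonormal rows), `eigenvalues`
#'   (nonincreasing, positive), `n_samples`, `n_requested`, `truncated`.
#' @examples
#' lib <- generate_library(generator_config(n_spectra = 12, seed = 1))
#' m <- fit_pca(lib, n_components = 3)
#' @export
fit_pca <- function(lib, n_components = 5) {
  x <- library_matrix(lib)
  n <- nrow(x)
  l <- ncol(x)
  if (n < 2) stop_config("PCA needs at least 2 calibration spectra.")
  if (n_components < 1 || n_components > min(n - 1, l)) {
    stop_config(sprintf(
      "n_components must be between 1 and min(N - 1, L) = %d.", min(n - 1, l)))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  thresh <- 1e-12 * max(eig, 0)
  p_rank <- sum(eig > thresh & eig > 0)
  p <- min(n_components, p_rank)
  truncated <- p < n_components
  if (truncated) {
    warn(sprintf(
      "calibration set has numerical rank %d < %d requested components; truncating.",
      p_rank, n_components))
  }
  comps <- if (p > 0) t(pc$rotation[, seq_len(p), drop = FALSE]) else
    matrix(0, 0, l)
  dimnames(comps) <- NULL
  # deterministic sign: largest-|element| entry of each component positive
  if (p > 0) {
    for (i in seq_len(p)) {
      j <- which.max(abs(comps[i, ]))
      if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
    }
  }
  structure(list(
    axis = library_axis(lib),
    mean = as.numeric(pc$center),
    components = comps,
    eigenvalues = eig[seq_len(p)],
    n_samples = n,
    n_requested = n_components,
    truncated = truncated
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> %d components (requested %d), N = %d spectra, L = %d points\n",
    nrow(x$components), x$n_requested, x$n_samples, length(x$mean)))
  if (length(x$eigenvalues)) {
    cat("eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  }
  invisible(x)
}

#' Project a spectrum onto a PCA model's components
#'
#' Returns the coordinates of `spec - mean` along each principal
#' component.
#'
#' @param model A [fit_pca()] model.
#' @param spec A spectrum on the model's axis, or a bare numeric vector
#'   of length L.
#' @return Numeric vector of P coefficients.
#' @export
project <- function(model, spec) {
  v <- spectrum_values(spec, length(model$mean))
  drop(model$components %*% (v - model$mean))
}

#' Reconstruct a spectrum from PCA coefficients
#'
#' @param model A [fit_pca()] model.
#' @param coeffs Numeric vector of P coefficients.
#' @return Numeric intensity vector `mean + sum(coeffs * components)`.
#' @export
reconstruct <- function(model, coeffs) {
  if (length(coeffs) != nrow(model$components)) {
    stop_dim("need one coefficient per model component.")
  }
  model$mean + drop(crossprod(model$components, coeffs))
}

# accept either a spectrum data frame or a bare numeric vector
spectrum_values <- function(spec, l_expected) {
  v <- if (is.data.frame(spec)) as_spectrum(spec)$intensity else
    as.numeric(spec)
  if (length(v) != l_expected) {
    stop_dim(sprintf("spectrum has %d points but the model expects %d.",
                     length(v), l_expected))
  }
  v
}
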