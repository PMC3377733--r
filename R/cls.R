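#' Build a least-squares design matrix from reference spectra
#'
#' Stacks the reference spectra as columns and optionally appends the
#' q + 1 basis columns of a q-th order polynomial background block
#' (`poly_order = -1` disables it). The polynomial basis is
#' Chebyshev-style, evaluated on the wavenumber axis mapped affinely to
#' \[-1, 1\]: raw powers of wavenumbers around 10^3 would make the normal
#' equations hopelessly ill-conditioned.
#'
#' @param references A list of spectra (data frames with `wavenumber`,
#'   `intensity`) sharing one axis, or a [spectral_library()] whose rows
#'   are the references.
#' @param poly_order Integer >= -1; degree of the polynomial block
#'   (3 gives the usual LS-3P background model).
#' @return An object of class `design_matrix`: list with `axis`,
#'   `columns` (L x K'), `roles` (tibble: column, role, degree),
#'   `poly_order`, `collinear` flag.
#' @export
build_design <- function(references, poly_order = 3) {
  if (inherits(references, "spectral_library")) {
    axis <- library_axis(references)
    refs <- t(library_matrix(references))
    labels <- library_labels(references)
  } else {
    specs <- lapply(references, as_spectrum)
    axis <- specs[[1]]$wavenumber
    for (s in specs[-1]) {
      if (length(s$wavenumber) != length(axis) ||
          any(abs(s$wavenumber - axis) > 1e-9 * pmax(abs(axis), 1))) {
        stop_dim("all reference spectra must share one axis.")
      }
    }
    refs <- vapply(specs, function(s) s$intensity, numeric(length(axis)))
    labels <- vapply(seq_along(specs), function(i) {
      attr(specs[[i]], "label") %||% paste0("ref", i)
    }, character(1))
  }
  poly_order <- as.integer(poly_order)
  if (poly_order < -1) stop_config("poly_order must be >= -1.")
  cols <- refs
  roles <- tibble(column = labels, role = "reference",
                  degree = NA_integer_)
  if (poly_order >= 0) {
    pb <- chebyshev_basis(axis, poly_order)
    cols <- cbind(cols, pb)
    roles <- dplyr::bind_rows(roles, tibble(
      column = paste0("poly", 0:poly_order),
      role = "polynomial",
      degree = 0:poly_order
    ))
  }
  colnames(cols) <- roles$column
  if (any(colSums(abs(cols)) == 0)) {
    stop_validation("design contains an all-zero column.")
  }
  collinear <- qr(cols)$rank < ncol(cols)
  if (collinear) {
    warn("design columns are collinear; the minimum-norm solution is used.")
  }
  structure(list(axis = axis, columns = cols, roles = roles,
                 poly_order = poly_order, collinear = collinear),
            class = "design_matrix")
}

# Chebyshev polynomials T_0..T_q on the axis rescaled to [-1, 1]
chebyshev_basis <- function(axis, order) {
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  out <- matrix(0, length(axis), order + 1)
  out[, 1] <- 1
  if (order >= 1) out[, 2] <- t
  if (order >= 2) {
    for (d in 2:order) out[, d + 1] <- 2 * t * out[, d] - out[, d - 1]
  }
  out
}

#' Classical least squares unmixing (LS-qP)
#'
#' Models the measured spectrum as a linear combination of the design
#' columns (reference spectra plus an optional polynomial background
#' block) and solves for the weights by the Moore-Penrose pseudoinverse
#' (minimum-norm least squares; relative singular-value cutoff 1e-12).
#' Negative weights are reported as-is, never clipped: their sign is
#' informative at low analyte strength.
#'
#' @param measured A spectrum on the design's axis, or a bare numeric
#'   vector of length L.
#' @param design A [build_design()] object.
#' @return An object of class `unmix_fit`: `method` (`"LS-qP"`),
#'   `weights` (named, reference columns), `poly_coeffs`, `fitted`,
#'   `residual`, `measured`, `axis`, `diagnostics` (list with
#'   `durbin_watson`, `collinear`).
#' @examples
#' axis <- seq(400, 1800, length.out = 200)
#' r1 <- spectrum(axis, exp(-(axis - 800)^2 / 200))
#' r2 <- spectrum(axis, exp(-(axis - 1200)^2 / 800))
#' d <- build_design(list(r1, r2), poly_order = -1)
#' fit <- cls_fit(0.25 * r1$intensity + r2$intensity, d)
#' fit$weights
#' @export
cls_fit <- function(measured, design) {
  m <- spectrum_values(measured, nrow(design$columns))
  sol <- pinv_solve(design$columns, m)
  fitted <- drop(design$columns %*% sol)
  residual <- m - fitted
  is_ref <- design$roles$role == "reference"
  weights <- stats::setNames(sol[is_ref], design$roles$column[is_ref])
  poly_coeffs <- sol[!is_ref]
  dw <- if (any(residual != 0)) durbin_watson(residual) else NA_real_
  structure(list(
    method = "LS-qP",
    weights = weights,
    poly_coeffs = poly_coeffs,
    fitted = fitted,
    residual = residual,
    measured = m,
    axis = design$axis,
    diagnostics = list(durbin_watson = dw, collinear = design$collinear)
  ), class = "unmix_fit")
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat(sprintf("<unmix_fit: %s>\n", x$method))
  cat("weights:\n")
  print(signif(x$weights, 6))
  if (!is.null(x$diagnostics$durbin_watson)) {
    cat(sprintf("Durbin-Watson: %.4f\n", x$diagnostics$durbin_watson))
  }
  invisible(x)
}
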