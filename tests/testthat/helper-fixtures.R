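# small in-code fixtures shared across tests

toy_axis <- function(l = 50) seq(400, 1800, length.out = l)

# a peaked toy spectrum on a given axis
toy_peak <- function(axis, center, width = 40, amplitude = 1) {
  amplitude * exp(-(axis - center)^2 / (2 * width^2))
}

# tiny deterministic calibration library: base shape plus `rank`
# orthonormal variation directions with Gaussian coefficients
toy_library <- function(axis = toy_axis(), n = 6, seed = 42,
                        direction = NULL, sd = 0.1, base = NULL,
                        rank = 3) {
  base <- base %||% (toy_peak(axis, 900) + 0.5 * toy_peak(axis, 1400, 80))
  dirs <- if (!is.null(direction)) {
    cbind(direction / sqrt(sum(direction^2)))
  } else {
    raw <- cbind(toy_peak(axis, 1100, 30),
                 toy_peak(axis, 700, 50),
                 toy_peak(axis, 1600, 45))[, seq_len(rank), drop = FALSE]
    qr.Q(qr(raw))
  }
  set.seed(seed)
  coefs <- matrix(rnorm(n * ncol(dirs), 0, sd), n)
  rows <- matrix(rep(base, each = n), n) + coefs %*% t(dirs)
  spectral_library(axis, rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a matrix-dialect delimited file and return the path
write_matrix_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
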