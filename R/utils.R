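#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Minimum-norm least-squares solve via the Moore-Penrose pseudoinverse.
# Singular values below rcond * max(singular value) are treated as zero.
pinv_solve <- function(A, b, rcond = 1e-12) {
  s <- svd(A)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) {
    return(numeric(ncol(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], b)) / s$d[keep]) |>
    drop()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_dim <- function(msg) abort(msg, class = "ramanmix_dimension_error")
stop_validation <- function(msg) abort(msg, class = "ramanmix_validation_error")
stop_config <- function(msg) abort(msg, class = "ramanmix_config_error")
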