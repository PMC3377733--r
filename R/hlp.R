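#' Configuration for the hybrid least-squares/PCA (HLP) estimator
#'
#' @param sigma Noise standard deviation of the measured signal, in
#'   intensity units; estimate it from replicate measurements with
#'   [estimate_sigma()]. Must be > 0.
#' @param max_iter Maximum number of alternation iterations (default
#'   500; convergence is typically observed within on the order of 100).
#' @param tol Relative weight-change convergence threshold:
#'   `max_k |w_k - w_k_prev| / max(max_k |w_k|, 1e-12) < tol`, default
#'   1e-8. The change is measured relative to the largest weight
#'   magnitude so that a weight fluctuating around zero (an analyte at
#'   trace concentration) does not stall convergence.
#' @param beta_override Optional penalty hyperparameter replacing the
#'   default `sigma^2`.
#' @return A list of class `hlp_config`.
#' @export
hlp_config <- function(sigma, max_iter = 500, tol = 1e-8,
                       beta_override = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop_config("`sigma` must be a single positive number.")
  }
  if (max_iter < 1) stop_config("`max_iter` must be >= 1.")
  if (tol <= 0) stop_config("`tol` must be > 0.")
  structure(list(sigma = sigma, max_iter = as.integer(max_iter),
                 tol = tol, beta_override = beta_override),
            class = "hlp_config")
}

#' Estimate the measurement noise level from replicate spectra
#'
#' Takes repeated measurements of the same static target and returns the
#' root of the mean (over wavelengths) per-wavelength sample variance
#' across replicates. A return of 0 (identical replicates) is degenerate:
#' HLP requires sigma > 0.
#'
#' @param replicates A [spectral_library()] of N >= 2 replicate
#'   measurements of one location.
#' @return A single nonnegative number in intensity units.
#' @export
estimate_sigma <- function(replicates) {
  x <- library_matrix(replicates)
  if (nrow(x) < 2) {
    stop_config("sigma estimation needs at least 2 replicate spectra.")
  }
  sqrt(mean(apply(x, 2, stats::var)))
}

#' Hybrid least-squares/PCA unmixing (HLP)
#'
#' Penalized maximum-likelihood unmixing in which each reference
#' spectrum flexes along the principal components of its calibration
#' set. The signal model is
#' \deqn{x = \sum_k w_k (\bar S_k + \sum_p c_{pk} Z_{pk})}
#' and the minimized cost is
#' \deqn{\|m - x\|^2 + \beta \sum_{k,p} c_{pk}^2 / \lambda_{pk}}
#' with \eqn{\beta = \sigma^2} by default: deviations from the mean are
#' allowed exactly to the extent the calibration set showed them
#' (eigenvalue \eqn{\lambda_{pk}} = observed variance along that
#' component).
#'
#' The cost is minimized by block alternation from zero-initialized
#' coefficients: a W-step (with C fixed, form the effective references
#' and solve for W by minimum-norm pseudoinverse) and a C-step (with W
#' fixed, a Tikhonov-regularized least squares with penalty matrix
#' \eqn{\Gamma = diag(\beta/\lambda_{pk})} on the residual after
#' removing the mean-spectrum contributions). Each half-step is an exact
#' block minimization, so the cost trace is nonincreasing.
#'
#' Components whose eigenvalue is numerically zero are excluded (the
#' infinite-penalty limit pins their coefficient to 0). If all weights
#' are zero at a C-step, the C-step is skipped for that iteration.
#'
#' @param measured A spectrum on the models' shared axis (or numeric
#'   vector of length L).
#' @param models A list of K [fit_pca()] models, one per compound
#'   (analyte(s) and background).
#' @param config An [hlp_config()].
#' @param n_components Optional integer (scalar or length K) limiting
#'   the number of components used per compound; default uses all
#'   components each model carries.
#' @return An object of class `hlp_fit` (also `unmix_fit`): `weights`,
#'   `coeffs` (list of per-compound coefficient vectors), `fitted`,
#'   `residual`, `effective_references` (L x K), `iterations`,
#'   `converged`, `cost_trace`, `diagnostics`.
#' @examples
#' lib <- generate_library(generator_config(n_spectra = 20, seed = 2))
#' bg <- generate_library(generator_config(
#'   peaks = data.frame(center = 1000, width = 60, amplitude = 1),
#'   n_spectra = 20, seed = 3))
#' ma <- fit_pca(lib, 3); mb <- fit_pca(bg, 3)
#' m <- 0.5 * ma$mean + mb$mean
#' fit <- hlp_fit(m, list(analyte = ma, background = mb),
#'                hlp_config(sigma = 0.02))
#' fit$weights
#' @export
hlp_fit <- function(measured, models, config, n_components = NULL) {
  stopifnot(inherits(config, "hlp_config"))
  k_n <- length(models)
  if (k_n < 1) stop_config("need at least one PCA model.")
  l <- length(models[[1]]$mean)
  for (mo in models) {
    if (length(mo$mean) != l) stop_dim("all models must share one axis length.")
  }
  m <- spectrum_values(measured, l)
  beta <- config$beta_override %||% config$sigma^2

  if (!is.null(n_components)) {
    n_components <- rep_len(as.integer(n_components), k_n)
  }
  means <- vapply(models, function(x) x$mean, numeric(l))
  # per-compound usable components: requested cap, then nonzero eigenvalues
  comp <- vector("list", k_n)
  lam <- vector("list", k_n)
  for (k in seq_len(k_n)) {
    p_avail <- nrow(models[[k]]$components)
    p_use <- if (is.null(n_components)) p_avail else
      min(n_components[k], p_avail)
    comp[[k]] <- models[[k]]$components[seq_len(p_use), , drop = FALSE]
    lam[[k]] <- models[[k]]$eigenvalues[seq_len(p_use)]
  }
  p_k <- vapply(comp, nrow, integer(1))
  p_tot <- sum(p_k)
  k_index <- rep(seq_len(k_n), p_k)
  # stack all components as a p_tot x L matrix for fast effective-reference
  # assembly; gamma holds the Tikhonov diagonal beta / lambda
  z_all <- do.call(rbind, comp)
  gamma <- beta / unlist(lam)

  w <- numeric(k_n)
  cc <- numeric(p_tot)
  cost <- function(w, cc) {
    eff <- effective_refs(means, z_all, cc, k_index, k_n)
    x <- drop(eff %*% w)
    sum((m - x)^2) + if (p_tot) sum(gamma * cc^2) else 0
  }
  cost_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w_prev <- w
    # W-step: plain least squares on the current effective references
    eff <- effective_refs(means, z_all, cc, k_index, k_n)
    w <- pinv_solve(eff, m)
    # C-step: Tikhonov-regularized solve on Q = m - sum_k w_k mean_k,
    # design columns (p, k) = w_k * Z_pk
    if (p_tot > 0 && any(w != 0)) {
      q <- m - drop(means %*% w)
      a <- t(z_all * w[k_index])           # L x p_tot
      ata <- crossprod(a)
      diag(ata) <- diag(ata) + gamma
      cc <- drop(solve(ata, crossprod(a, q)))
    }
    cost_trace <- c(cost_trace, cost(w, cc))
    # convergence of the weight vector: largest absolute change relative
    # to the largest weight magnitude. A per-component relative change
    # never settles when a weight hovers around zero (as the analyte
    # weight does at trace concentrations), so the vector-relative form
    # is used.
    delta <- max(abs(w - w_prev)) / max(abs(w), 1e-12)
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
    if (iter >= config$max_iter) break
  }

  eff <- effective_refs(means, z_all, cc, k_index, k_n)
  fitted <- drop(eff %*% w)
  residual <- m - fitted
  names(w) <- names(models) %||% paste0("compound", seq_len(k_n))
  coeffs <- split(cc, factor(k_index, levels = seq_len(k_n)))
  names(coeffs) <- names(w)
  dw <- if (any(residual != 0)) durbin_watson(residual) else NA_real_
  structure(list(
    method = "HLP",
    weights = w,
    coeffs = coeffs,
    fitted = fitted,
    residual = residual,
    measured = m,
    axis = models[[1]]$axis,
    effective_references = eff,
    iterations = iter,
    converged = converged,
    cost_trace = cost_trace,
    beta = beta,
    diagnostics = list(durbin_watson = dw, iterations = iter,
                       converged = converged)
  ), class = c("hlp_fit", "unmix_fit"))
}

# L x K matrix of S_bar_k + sum_p c_pk Z_pk
effective_refs <- function(means, z_all, cc, k_index, k_n) {
  eff <- means
  if (length(cc)) {
    adj <- rowsum(z_all * cc, group = k_index)     # per-compound sum, rows
    eff[, as.integer(rownames(adj))] <-
      eff[, as.integer(rownames(adj))] + t(adj)
  }
  eff
}

#' Convert a fitted weight to a concentration
#'
#' A weight of 1 corresponds to the concentration of the solution from
#' which the reference spectrum was measured.
#'
#' @param weight Fitted weight (dimensionless multiple of the
#'   reference).
#' @param ref_concentration Reference solution concentration (> 0), in
#'   the units of the answer (e.g. 0.8 nM).
#' @return `weight * ref_concentration`.
#' @examples
#' weight_to_concentration(2^-3, 0.8) # 0.1
#' @export
weight_to_concentration <- function(weight, ref_concentration) {
  if (any(ref_concentration <= 0)) {
    stop_config("`ref_concentration` must be > 0.")
  }
  weight * ref_concentration
}
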