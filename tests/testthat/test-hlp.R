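# hand-built PCA models with known components, for solver tests
toy_model <- function(axis, mean, dirs, eigenvalues) {
  q <- qr.Q(qr(dirs))                 # orthonormalize columns
  comps <- t(q)
  for (i in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(list(axis = axis, mean = mean, components = comps,
                 eigenvalues = eigenvalues, n_samples = 10L,
                 n_requested = nrow(comps), truncated = FALSE),
            class = "pca_model")
}

zero_var_model <- function(axis, mean) {
  structure(list(axis = axis, mean = mean,
                 components = matrix(0, 0, length(axis)),
                 eigenvalues = numeric(0), n_samples = 5L,
                 n_requested = 0L, truncated = TRUE),
            class = "pca_model")
}

test_that("estimate_sigma matches closed forms and the large-N limit", {
  axis <- toy_axis(20)
  base <- toy_peak(axis, 900)
  identical_lib <- spectral_library(axis, rbind(base, base, base))
  expect_equal(estimate_sigma(identical_lib), 0)

  # two replicates offset by delta everywhere: sd = delta / sqrt(2)
  delta <- 0.3
  lib2 <- spectral_library(axis, rbind(base, base + delta))
  expect_equal(estimate_sigma(lib2), delta / sqrt(2), tolerance = 1e-12)

  set.seed(4)
  sigma0 <- 0.05
  n <- 200; l <- 700
  noisy <- matrix(2 + rnorm(n * l, 0, sigma0), n, l)
  est <- estimate_sigma(spectral_library(seq_len(l), noisy))
  expect_lt(abs(est - sigma0) / sigma0, 0.05)

  expect_error(estimate_sigma(spectral_library(axis, rbind(base))),
               class = "ramanmix_config_error")
})

test_that("with zero-variance models HLP collapses to CLS on the means", {
  axis <- toy_axis(40)
  m1 <- toy_peak(axis, 800, 30)
  m2 <- toy_peak(axis, 1300, 100) + 0.2
  models <- list(a = zero_var_model(axis, m1), b = zero_var_model(axis, m2))
  set.seed(6)
  m <- 0.4 * m1 + 0.9 * m2 + rnorm(length(axis), 0, 0.05)
  fit <- hlp_fit(m, models, hlp_config(sigma = 0.05))
  cls <- cls_fit(m, build_design(list(spectrum(axis, m1),
                                      spectrum(axis, m2)),
                                 poly_order = -1))
  expect_equal(unname(fit$weights), unname(cls$weights),
               tolerance = 1e-10)
})

test_that("exact mean mixtures are recovered with near-zero coefficients", {
  lib_a <- toy_library(n = 8, seed = 1, sd = 0.2)
  lib_b <- toy_library(n = 8, seed = 2, sd = 0.2,
                       base = toy_peak(toy_axis(), 1250, 120) + 0.3)
  ma <- fit_pca(lib_a, 3)
  mb <- fit_pca(lib_b, 3)
  m <- 0.3 * ma$mean + 1.0 * mb$mean
  fit <- hlp_fit(m, list(ma, mb), hlp_config(sigma = 0.01))
  expect_lt(max(abs(unname(fit$weights) - c(0.3, 1.0))), 1e-6)
  expect_lt(max(abs(unlist(fit$coeffs))), 1e-4)
  expect_equal(fit$fitted + fit$residual, fit$measured, tolerance = 1e-10)
})

test_that("the alternation reaches the brute-force optimum on K=2 P=2 toys", {
  l <- 12
  axis <- seq_len(l)
  set.seed(31)
  for (trial in 1:4) {
    mean1 <- abs(rnorm(l, 1, 0.3)); mean2 <- abs(rnorm(l, 1, 0.3))
    mod1 <- toy_model(axis, mean1, matrix(rnorm(2 * l), l, 2), c(0.5, 0.1))
    mod2 <- toy_model(axis, mean2, matrix(rnorm(2 * l), l, 2), c(0.3, 0.05))
    true_c1 <- rnorm(2, 0, sqrt(mod1$eigenvalues))
    true_c2 <- rnorm(2, 0, sqrt(mod2$eigenvalues))
    m <- 0.6 * (mean1 + drop(crossprod(mod1$components, true_c1))) +
      1.1 * (mean2 + drop(crossprod(mod2$components, true_c2))) +
      rnorm(l, 0, 0.02)
    sigma <- 0.02
    cfg <- hlp_config(sigma = sigma, max_iter = 2000, tol = 1e-12)
    fit <- hlp_fit(m, list(mod1, mod2), cfg)

    beta <- sigma^2
    cost_fn <- function(par) {
      w <- par[1:2]; c1 <- par[3:4]; c2 <- par[5:6]
      x <- w[1] * (mean1 + drop(crossprod(mod1$components, c1))) +
        w[2] * (mean2 + drop(crossprod(mod2$components, c2)))
      sum((m - x)^2) + beta * (sum(c1^2 / mod1$eigenvalues) +
                                 sum(c2^2 / mod2$eigenvalues))
    }
    # black-box minimization from multiple restarts
    best <- Inf
    for (r in 1:8) {
      start <- rnorm(6, 0, 0.5)
      opt <- optim(start, cost_fn, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15))
      best <- min(best, opt$value)
    }
    final_cost <- tail(fit$cost_trace, 1)
    expect_lt(abs(final_cost - best), 1e-8)
  }
})

test_that("the penalized cost descends monotonically", {
  lib_a <- toy_library(n = 10, seed = 3, sd = 0.3)
  ma <- fit_pca(lib_a, 3)
  mb <- fit_pca(toy_library(n = 10, seed = 4, sd = 0.4,
                            base = toy_peak(toy_axis(), 1200, 150) + 0.2), 3)
  set.seed(55)
  for (trial in 1:5) {
    m <- runif(1, 0.01, 1) * library_matrix(lib_a)[1, ] + mb$mean +
      rnorm(length(ma$mean), 0, 0.05)
    fit <- hlp_fit(m, list(ma, mb), hlp_config(sigma = 0.05))
    expect_true(all(diff(fit$cost_trace) <=
                      1e-9 * pmax(abs(fit$cost_trace[-1]), 1)))
  }
})

test_that("beta limits bracket the model between CLS and interpolation", {
  lib_a <- toy_library(n = 8, seed = 7, sd = 0.3)
  ma <- fit_pca(lib_a, 3)
  mb <- fit_pca(toy_library(n = 8, seed = 8, sd = 0.3,
                            base = toy_peak(toy_axis(), 1150, 140) + 0.25), 3)
  axis <- ma$axis
  # noiseless perturbed measurement, perturbation within the PC spans
  pert_a <- drop(crossprod(ma$components, c(0.2, -0.1, 0.05)))
  m <- 0.5 * (ma$mean + pert_a) + mb$mean

  # beta -> infinity: coefficients forced to zero, CLS on the means
  big <- hlp_fit(m, list(ma, mb),
                 hlp_config(sigma = 1, beta_override = 1e12))
  cls <- cls_fit(m, build_design(list(spectrum(axis, ma$mean),
                                      spectrum(axis, mb$mean)),
                                 poly_order = -1))
  expect_lt(max(abs(unname(big$weights) - unname(cls$weights))), 1e-6)
  expect_lt(max(abs(unlist(big$coeffs))), 1e-8)

  # beta -> 0 with the spanning components: residual vanishes
  tiny <- hlp_fit(m, list(ma, mb),
                  hlp_config(sigma = 1, beta_override = 1e-12,
                             max_iter = 2000, tol = 1e-12))
  expect_lt(sqrt(sum(tiny$residual^2)), 1e-5 * sqrt(sum(m^2)))
})

test_that("weight-concentration conversion is plain scaling", {
  expect_equal(weight_to_concentration(1.0, 0.8), 0.8)
  expect_equal(weight_to_concentration(2^-3, 0.8), 0.1)
  expect_equal(weight_to_concentration(0, 5), 0)
  expect_error(weight_to_concentration(1, 0), class = "ramanmix_config_error")
})

test_that("config validation rejects impossible settings", {
  expect_error(hlp_config(sigma = 0), class = "ramanmix_config_error")
  expect_error(hlp_config(sigma = 1, max_iter = 0),
               class = "ramanmix_config_error")
  expect_error(hlp_config(sigma = 1, tol = -1),
               class = "ramanmix_config_error")
})
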