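test_that("a zero-variance library yields a truncated P = 0 model", {
  axis <- toy_axis(30)
  base <- toy_peak(axis, 900)
  lib <- spectral_library(axis, matrix(rep(base, 5), 5, byrow = TRUE))
  expect_warning(model <- fit_pca(lib, 2), "rank")
  expect_equal(length(model$eigenvalues), 0)
  expect_true(model$truncated)
  expect_equal(model$mean, base)
})

test_that("N = 2 model matches the hand eigendecomposition", {
  axis <- toy_axis(25)
  a <- toy_peak(axis, 800)
  b <- toy_peak(axis, 1200, 60)
  lib <- spectral_library(axis, rbind(a, b))
  model <- fit_pca(lib, 1)
  d <- (a - b) / sqrt(sum((a - b)^2))
  # sign convention may flip the direction
  expect_lt(min(max(abs(model$components[1, ] - d)),
                max(abs(model$components[1, ] + d))), 1e-10)
  expect_equal(model$eigenvalues[1], sum((a - b)^2) / 2,
               tolerance = 1e-10)
})

test_that("eigenvalues equal projection variances; components orthonormal", {
  lib <- toy_library(n = 10, sd = 0.3)
  model <- fit_pca(lib, 3)
  x <- library_matrix(lib)
  centered <- sweep(x, 2, model$mean)
  for (p in seq_along(model$eigenvalues)) {
    proj <- centered %*% model$components[p, ]
    expect_equal(stats::var(drop(proj)), model$eigenvalues[p],
                 tolerance = 1e-10)
  }
  gram <- model$components %*% t(model$components)
  expect_lt(max(abs(gram - diag(nrow(gram)))), 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
})

test_that("fit is invariant to row order and bounded by total variance", {
  lib <- toy_library(n = 8, sd = 0.2)
  x <- library_matrix(lib)
  set.seed(3)
  shuffled <- spectral_library(library_axis(lib),
                               x[sample(nrow(x)), , drop = FALSE])
  m1 <- fit_pca(lib, 3)
  m2 <- fit_pca(shuffled, 3)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-10)
  expect_equal(m1$components, m2$components, tolerance = 1e-8)

  total_var <- sum(apply(x, 2, stats::var))
  expect_lte(sum(m1$eigenvalues), total_var + 1e-10)
})

test_that("components recover a known low-rank generating subspace", {
  axis <- toy_axis(80)
  d1 <- toy_peak(axis, 700, 30); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- toy_peak(axis, 1500, 50)
  d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  base <- toy_peak(axis, 1000, 100)
  set.seed(9)
  n <- 400
  rows <- t(vapply(seq_len(n), function(i) {
    base + rnorm(1, 0, 1) * d1 + rnorm(1, 0, 0.5) * d2
  }, numeric(length(axis))))
  model <- fit_pca(spectral_library(axis, rows), 2)
  # principal angles between fitted and true subspaces
  sv <- svd(model$components %*% cbind(d1, d2))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
})

test_that("project and reconstruct satisfy the projection identities", {
  lib <- toy_library(n = 7, sd = 0.25)
  model <- fit_pca(lib, 3)
  p <- length(model$eigenvalues)

  expect_equal(project(model, model$mean), rep(0, p))

  probe <- model$mean + 3 * model$components[1, ]
  expect_equal(project(model, probe), c(3, rep(0, p - 1)),
               tolerance = 1e-10)

  spec <- library_matrix(lib)[2, ]
  coef <- project(model, spec)
  resid <- spec - reconstruct(model, coef)
  expect_lt(max(abs(model$components %*% resid)), 1e-10)

  expect_error(project(model, 1:3), class = "ramanmix_dimension_error")
})

test_that("requesting too many components is a configuration error", {
  lib <- toy_library(n = 4)
  expect_error(fit_pca(lib, 10), class = "ramanmix_config_error")
  expect_error(fit_pca(lib, 0), class = "ramanmix_config_error")
})

test_that("PCA models round-trip through JSON serialization", {
  model <- fit_pca(toy_library(n = 6, sd = 0.2), 3)
  path <- tempfile(fileext = ".json")
  write_pca_model(model, path)
  back <- read_pca_model(path)
  expect_equal(back$mean, model$mean, tolerance = 1e-12)
  expect_equal(back$components, model$components, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$eigenvalues, model$eigenvalues, tolerance = 1e-12)
  expect_equal(back$n_samples, model$n_samples)
})
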