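test_that("the generator is degenerate and deterministic when asked", {
  cfg0 <- generator_config(amplitude_jitter = 0, shift_jitter = 0,
                           noise_sigma = 0, n_spectra = 10, seed = 3)
  lib0 <- generate_library(cfg0)
  x <- library_matrix(lib0)
  expect_equal(max(apply(x, 2, function(col) diff(range(col)))), 0)

  cfg <- generator_config(n_spectra = 6, seed = 77)
  expect_identical(library_matrix(generate_library(cfg)),
                   library_matrix(generate_library(cfg)))
  # a different seed gives different spectra
  cfg2 <- generator_config(n_spectra = 6, seed = 78)
  expect_false(identical(library_matrix(generate_library(cfg)),
                         library_matrix(generate_library(cfg2))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(generate_library(generator_config(n_spectra = 3, seed = 9)))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("amplitude-only jitter concentrates variance on the peak shape", {
  cfg <- generator_config(
    peaks = data.frame(center = 1000, width = 40, amplitude = 1),
    amplitude_jitter = 0.2, shift_jitter = 0, noise_sigma = 0,
    n_spectra = 300, seed = 5)
  lib <- generate_library(cfg)
  model <- suppressWarnings(fit_pca(lib, 1))
  axis <- library_axis(lib)
  shape <- exp(-(axis - 1000)^2 / (2 * 40^2))
  shape <- shape / sqrt(sum(shape^2))
  expect_gte(abs(sum(model$components[1, ] * shape)), 0.99)
})

test_that("the combination count follows the factorial arithmetic", {
  a <- generate_library(generator_config(n_spectra = 5, seed = 1))
  b <- generate_library(background_generator_config(n_spectra = 6, seed = 2))
  cfg <- study_config(a, b)
  expect_equal(n_combinations(cfg), 14 * 5 * 6)  # 420

  # the published-scale grid: 14 levels x 106 x 476 spectra
  cfg_big <- study_config(a, b, subsample = c(106, 476))
  n_a <- 106; n_b <- 476
  expect_equal(14 * n_a * n_b, 706384)
})

test_that("zero-variability libraries are unmixed exactly by all methods", {
  axis <- toy_axis(120)
  a_base <- toy_peak(axis, 700, 25) + toy_peak(axis, 1000, 15)
  b_base <- toy_peak(axis, 1250, 120) + 0.4
  a <- spectral_library(axis, matrix(rep(a_base, 4), 4, byrow = TRUE))
  b <- spectral_library(axis, matrix(rep(b_base, 5), 5, byrow = TRUE))
  s <- suppressWarnings(run_factorial_study(study_config(
    a, b, weight_levels = 2^(0:-5), subsample = c(2, 2))))
  expect_lt(max(abs(s$records$fractional_error)), 1e-6)
})

test_that("study records and summaries are internally consistent", {
  a <- generate_library(generator_config(n_spectra = 4, seed = 31))
  b <- generate_library(background_generator_config(n_spectra = 4, seed = 32))
  s <- run_factorial_study(study_config(
    a, b, weight_levels = c(1, 0.25), methods = c("LS-3P", "HLA")))
  expect_equal(s$n_combinations, 2 * 4 * 4)
  expect_equal(nrow(s$records), s$n_combinations * 2)

  # summary totals re-derived by an independent aggregation pass
  for (meth in c("LS-3P", "HLA")) {
    for (v in c(1, 0.25)) {
      sub <- s$records[s$records$method == meth &
                         s$records$true_weight == v, ]
      row <- s$summaries[s$summaries$method == meth &
                           s$summaries$true_weight == v, ]
      expect_equal(row$n, nrow(sub))
      expect_equal(row$mean_fractional_error, mean(sub$fractional_error),
                   tolerance = 1e-12)
      expect_equal(row$sd_fractional_error, stats::sd(sub$fractional_error),
                   tolerance = 1e-12)
    }
  }
})

test_that("two-point and single-record summaries use n-1 conventions", {
  rec <- tibble::tibble(
    method = c("m", "m", "solo"),
    true_weight = c(0.5, 0.5, 0.5),
    fractional_error = c(-0.1, 0.1, 0.2),
    durbin_watson = c(2, 2, 2))
  s <- summarize_study(rec)
  two <- s[s$method == "m", ]
  expect_equal(two$mean_fractional_error, 0)
  expect_equal(two$sd_fractional_error, sqrt(0.02 / 1), tolerance = 1e-10)
  solo <- s[s$method == "solo", ]
  expect_equal(solo$sd_fractional_error, 0)
  expect_true(solo$single_record)
})

test_that("a single-spectrum library cannot run leave-one-out", {
  axis <- toy_axis(30)
  one <- spectral_library(axis, rbind(toy_peak(axis, 900)))
  many <- toy_library(axis = axis, n = 4)
  expect_error(run_factorial_study(study_config(one, many)),
               class = "ramanmix_config_error")
})
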