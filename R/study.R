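#' Configuration for the factorial estimator-comparison study
#'
#' The study mirrors a leave-one-out characterization protocol: for
#' every combination of one analyte spectrum, one background spectrum,
#' and one weight level, a measurement is simulated as
#' `weight * analyte + background` (backgrounds are never weighted); the
#' methods are calibrated on the remaining spectra of each library and
#' asked to recover the weight.
#'
#' @param analyte_library,background_library [spectral_library()]s on a
#'   shared axis, each with N >= 2 spectra.
#' @param weight_levels Strictly decreasing positive weights; default
#'   the halving ladder `2^0, 2^-1, ..., 2^-13` (14 levels).
#' @param n_components Components per PCA model (default 5).
#' @param ref_concentration Concentration of the reference solution
#'   (default 0.8, in nM for the default scenario).
#' @param methods Subset of `c("LS-3P", "HLA", "HLP")`.
#' @param sigma Noise sd handed to HLP; default 0.02, the synthetic
#'   generator's default noise level.
#' @param subsample Optional `c(n_analyte, n_background)` cap: only the
#'   first so many spectra of each library enter the factorial grid
#'   (calibration still uses the full remaining libraries).
#' @param poly_order Polynomial order for the LS-qP comparator
#'   (default 3).
#' @param seed Integer seed (reserved for stochastic extensions; the
#'   study itself is deterministic given its libraries).
#' @return A list of class `study_config`.
#' @export
study_config <- function(analyte_library, background_library,
                         weight_levels = 2^(0:-13),
                         n_components = 5,
                         ref_concentration = 0.8,
                         methods = c("LS-3P", "HLA", "HLP"),
                         sigma = 0.02,
                         subsample = NULL,
                         poly_order = 3,
                         seed = 1L) {
  if (any(diff(weight_levels) >= 0) || any(weight_levels <= 0)) {
    stop_config("`weight_levels` must be strictly decreasing and positive.")
  }
  methods <- match.arg(methods, c("LS-3P", "HLA", "HLP"),
                       several.ok = TRUE)
  if (!isTRUE(all.equal(library_axis(analyte_library),
                        library_axis(background_library)))) {
    stop_config("analyte and background libraries must share one axis.")
  }
  if (!is.null(subsample)) {
    subsample <- as.integer(rep_len(subsample, 2))
    if (any(subsample < 1)) stop_config("`subsample` entries must be >= 1.")
  }
  structure(list(
    analyte_library = analyte_library,
    background_library = background_library,
    weight_levels = as.numeric(weight_levels),
    n_components = as.integer(n_components),
    ref_concentration = ref_concentration,
    methods = methods, sigma = sigma, subsample = subsample,
    poly_order = as.integer(poly_order), seed = as.integer(seed)
  ), class = "study_config")
}

#' Number of factorial combinations a study configuration spans
#'
#' `|weight_levels| * n_analyte_used * n_background_used`, respecting
#' any `subsample` cap.
#'
#' @param config A [study_config()].
#' @return Integer (double for very large grids).
#' @examples
#' # 14 levels x 106 analyte x 476 background spectra -> 706,384
#' @export
n_combinations <- function(config) {
  n_a <- n_spectra(config$analyte_library)
  n_b <- n_spectra(config$background_library)
  if (!is.null(config$subsample)) {
    n_a <- min(n_a, config$subsample[1])
    n_b <- min(n_b, config$subsample[2])
  }
  length(config$weight_levels) * n_a * n_b
}

#' Run the leave-one-out factorial comparison study
#'
#' For every (analyte i, background j, weight v) combination the
#' simulated measurement is `v * analyte_i + background_j`. Calibration
#' is leave-one-out: the analyte model/reference comes from all analyte
#' spectra except i, the background model/mean from all background
#' spectra except j. Leave-one-out PCA models are computed once per
#' excluded index and cached (N_a + N_b fits, not N_a x N_b).
#'
#' Per record the estimated weight, the concentration via
#' `ref_concentration`, the signed fractional error, and the
#' Durbin-Watson statistic of the fit residual are stored; for HLP also
#' the iteration count, convergence flag, and whether the cost trace was
#' nonincreasing.
#'
#' @param config A [study_config()].
#' @return An object of class `study_result`: `records` (tibble: method,
#'   analyte_idx, background_idx, true_weight, estimated_weight,
#'   true_concentration, estimated_concentration, fractional_error,
#'   durbin_watson, iterations, converged, cost_monotone),
#'   `summaries` (see [summarize_study()]), `n_combinations`, `config`.
#' @export
run_factorial_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  a_lib <- config$analyte_library
  b_lib <- config$background_library
  if (n_spectra(a_lib) < 2 || n_spectra(b_lib) < 2) {
    stop_config("leave-one-out needs at least 2 spectra per library.")
  }
  a_mat <- library_matrix(a_lib)
  b_mat <- library_matrix(b_lib)
  axis <- library_axis(a_lib)
  n_a_used <- if (is.null(config$subsample)) nrow(a_mat) else
    min(nrow(a_mat), config$subsample[1])
  n_b_used <- if (is.null(config$subsample)) nrow(b_mat) else
    min(nrow(b_mat), config$subsample[2])

  loo_fit <- function(rest) {
    if (nrow(rest) == 1) {
      # a single remaining spectrum carries no variability information
      model <- structure(list(
        axis = axis, mean = rest[1, ],
        components = matrix(0, 0, ncol(rest)),
        eigenvalues = numeric(0), n_samples = 1L,
        n_requested = config$n_components, truncated = TRUE
      ), class = "pca_model")
      return(list(model = model, mean = rest[1, ]))
    }
    nc <- max(1L, min(config$n_components, nrow(rest) - 1L, length(axis)))
    list(model = fit_pca(spectral_library(axis, rest), nc),
         mean = colMeans(rest))
  }
  loo_analyte <- lapply(seq_len(n_a_used), function(i) {
    loo_fit(a_mat[-i, , drop = FALSE])
  })
  loo_background <- lapply(seq_len(n_b_used), function(j) {
    loo_fit(b_mat[-j, , drop = FALSE])
  })

  hlp_cfg <- hlp_config(sigma = config$sigma)
  levels_v <- config$weight_levels
  rows <- vector("list", n_a_used * n_b_used * length(levels_v) *
                   length(config$methods))
  r <- 0L
  for (i in seq_len(n_a_used)) {
    cal_a <- loo_analyte[[i]]
    for (j in seq_len(n_b_used)) {
      cal_b <- loo_background[[j]]
      design <- if ("LS-3P" %in% config$methods) {
        build_design(
          list(spectrum(axis, cal_a$mean, "analyte"),
               spectrum(axis, cal_b$mean, "background")),
          poly_order = config$poly_order)
      }
      calib <- if ("HLA" %in% config$methods) {
        hla_calibrate(cal_b$model, cal_a$mean)
      }
      models <- list(analyte = cal_a$model, background = cal_b$model)
      for (v in levels_v) {
        m <- v * a_mat[i, ] + b_mat[j, ]
        for (meth in config$methods) {
          est <- switch(meth,
            "LS-3P" = {
              fit <- cls_fit(m, design)
              list(w = unname(fit$weights[1]),
                   dw = fit$diagnostics$durbin_watson,
                   iter = NA_integer_, conv = NA, mono = NA)
            },
            "HLA" = {
              fit <- hla_estimate(m, calib,
                                  ref_concentration = 1,
                                  background_model = cal_b$model,
                                  analyte_ref = cal_a$mean)
              list(w = fit$weight,
                   dw = fit$diagnostics$durbin_watson,
                   iter = NA_integer_, conv = NA, mono = NA)
            },
            "HLP" = {
              fit <- hlp_fit(m, models, hlp_cfg)
              list(w = unname(fit$weights[1]),
                   dw = fit$diagnostics$durbin_watson,
                   iter = fit$iterations, conv = fit$converged,
                   mono = !any(diff(fit$cost_trace) > 1e-9 *
                                 pmax(abs(fit$cost_trace[-1]), 1)))
            })
          r <- r + 1L
          rows[[r]] <- tibble(
            method = meth, analyte_idx = i, background_idx = j,
            true_weight = v, estimated_weight = est$w,
            true_concentration = v * config$ref_concentration,
            estimated_concentration =
              weight_to_concentration(est$w, config$ref_concentration),
            fractional_error = fractional_error(
              est$w * config$ref_concentration,
              v * config$ref_concentration),
            durbin_watson = est$dw,
            iterations = est$iter, converged = est$conv,
            cost_monotone = est$mono
          )
        }
      }
    }
  }
  records <- dplyr::bind_rows(rows)
  out <- structure(list(
    records = records,
    summaries = NULL,
    n_combinations = length(levels_v) * n_a_used * n_b_used,
    config = config
  ), class = "study_result")
  out$summaries <- summarize_study(out)
  out
}

#' Summarize a factorial study
#'
#' Per (method, weight level): mean and sample standard deviation
#' (denominator n - 1; 0 with a flag when n = 1) of the signed
#' fractional error, mean absolute fractional error, and mean
#' Durbin-Watson.
#'
#' @param result A [run_factorial_study()] result, or any data frame
#'   with the same record columns.
#' @return A tibble with columns `method`, `true_weight`, `n`,
#'   `mean_fractional_error`, `sd_fractional_error`,
#'   `mean_abs_fractional_error`, `mean_dw`, `single_record`.
#' @export
summarize_study <- function(result) {
  records <- if (inherits(result, "study_result")) result$records else
    as_tibble(result)
  stopifnot(nrow(records) > 0)
  records |>
    dplyr::group_by(.data$method, .data$true_weight) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fractional_error = mean(.data$fractional_error),
      sd_fractional_error = ifelse(dplyr::n() > 1,
                                   stats::sd(.data$fractional_error), 0),
      mean_abs_fractional_error = mean(abs(.data$fractional_error)),
      mean_dw = mean(.data$durbin_watson),
      single_record = dplyr::n() == 1,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$method, dplyr::desc(.data$true_weight))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d combinations, %d records, methods: %s\n",
              x$n_combinations, nrow(x$records),
              paste(unique(x$records$method), collapse = ", ")))
  print(x$summaries, n = 10)
  invisible(x)
}
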