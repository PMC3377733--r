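#' Construct a single spectrum
#'
#' A spectrum pairs a strictly increasing wavenumber axis (cm^-1) with an
#' intensity vector in arbitrary detector units. It is stored as a tibble
#' with columns `wavenumber` and `intensity`, so it composes directly with
#' dplyr/ggplot2 pipelines.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of intensities, same length, all finite.
#' @param label Optional character identifier, kept as the `"label"`
#'   attribute.
#' @return A tibble of class `raman_spectrum` with columns `wavenumber`
#'   and `intensity`.
#' @examples
#' s <- spectrum(c(400, 500, 600), c(1, 2, 1.5))
#' @export
spectrum <- function(wavenumber, intensity, label = NULL) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  validate_axis(wavenumber)
  if (length(intensity) != length(wavenumber)) {
    stop_validation("`wavenumber` and `intensity` must have equal length.")
  }
  if (!all(is.finite(intensity))) {
    stop_validation("all intensities must be finite.")
  }
  out <- tibble(wavenumber = wavenumber, intensity = intensity)
  class(out) <- c("raman_spectrum", class(out))
  attr(out, "label") <- label
  out
}

#' Coerce a data frame to a spectrum
#'
#' @param x A data frame with columns `wavenumber` and `intensity`, or a
#'   `raman_spectrum`.
#' @return A validated `raman_spectrum`.
#' @export
as_spectrum <- function(x) {
  if (inherits(x, "raman_spectrum")) {
    return(spectrum(x$wavenumber, x$intensity, attr(x, "label")))
  }
  if (!is.data.frame(x) || !all(c("wavenumber", "intensity") %in% names(x))) {
    stop_validation(
      "a spectrum needs `wavenumber` and `intensity` columns.")
  }
  spectrum(x$wavenumber, x$intensity, attr(x, "label"))
}

validate_axis <- function(axis) {
  if (length(axis) < 2) {
    stop_validation("the wavenumber axis needs at least 2 points.")
  }
  if (!all(is.finite(axis))) {
    stop_validation("the wavenumber axis must be finite.")
  }
  if (any(diff(axis) <= 0)) {
    stop_validation("the wavenumber axis must be strictly increasing.")
  }
  invisible(axis)
}

#' Construct a spectral library
#'
#' A calibration library stores N replicate spectra of one material on a
#' shared wavenumber axis. It is a wide tibble: a `wavenumber` column
#' followed by one intensity column per spectrum, rows ordered by
#' ascending wavenumber.
#'
#' @param axis Shared wavenumber axis, strictly increasing.
#' @param intensities N x L numeric matrix, one row per replicate
#'   spectrum (L = length of axis).
#' @param labels Optional character vector of N column labels; defaults
#'   to `s1..sN`.
#' @return A tibble of class `spectral_library`.
#' @examples
#' lib <- spectral_library(1:5, rbind(1:5, 2:6))
#' @export
spectral_library <- function(axis, intensities, labels = NULL) {
  axis <- as.numeric(axis)
  validate_axis(axis)
  intensities <- rbind(intensities)
  if (ncol(intensities) != length(axis)) {
    stop_validation("each spectrum must have one intensity per axis point.")
  }
  if (nrow(intensities) < 1) {
    stop_validation("a spectral library needs at least one spectrum.")
  }
  if (!all(is.finite(intensities))) {
    stop_validation("all library intensities must be finite.")
  }
  labels <- labels %||% paste0("s", seq_len(nrow(intensities)))
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  out <- tibble(wavenumber = axis)
  mat <- t(intensities)
  colnames(mat) <- labels
  out <- dplyr::bind_cols(out, as_tibble(mat))
  class(out) <- c("spectral_library", class(out))
  out
}

#' @rdname spectral_library
#' @param x A data frame whose first column is `wavenumber` and whose
#'   remaining columns are spectra.
#' @export
as_spectral_library <- function(x) {
  if (!is.data.frame(x) || !"wavenumber" %in% names(x)) {
    stop_validation("a spectral library needs a `wavenumber` column.")
  }
  cols <- setdiff(names(x), "wavenumber")
  spectral_library(
    x$wavenumber,
    t(as.matrix(x[cols])),
    labels = cols
  )
}

#' Accessors for spectral libraries
#'
#' `library_axis()` returns the shared wavenumber axis; `library_matrix()`
#' the N x L intensity matrix (one row per spectrum); `library_labels()`
#' the spectrum labels; `library_spectrum()` extracts one spectrum.
#'
#' @param lib A `spectral_library`.
#' @return See above.
#' @export
library_axis <- function(lib) lib$wavenumber

#' @rdname library_axis
#' @export
library_matrix <- function(lib) {
  cols <- setdiff(names(lib), "wavenumber")
  m <- t(as.matrix(lib[cols]))
  rownames(m) <- cols
  m
}

#' @rdname library_axis
#' @export
library_labels <- function(lib) setdiff(names(lib), "wavenumber")

#' @rdname library_axis
#' @param i Spectrum index or label.
#' @export
library_spectrum <- function(lib, i) {
  labs <- library_labels(lib)
  if (is.numeric(i)) i <- labs[i]
  if (is.na(i) || !i %in% labs) stop_validation("no such spectrum in library.")
  spectrum(lib$wavenumber, lib[[i]], label = i)
}

#' Number of spectra in a library
#' @param lib A `spectral_library`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(lib) length(library_labels(lib))

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"), function(d) {
    lengths(regmatches(first, gregexpr(d, first, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0)) stop_validation(
    sprintf("no delimiter (comma/tab/semicolon) found in '%s'.", path))
  c(",", "\t", ";")[which.max(counts)]
}

parse_numeric_cells <- function(chr_mat, path) {
  num <- suppressWarnings(apply(chr_mat, 2, as.numeric))
  num <- rbind(num)
  bad <- which(is.na(num) & !is.na(chr_mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric cell '%s' at data row %d, column %d of '%s'.",
      chr_mat[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path),
      class = "ramanmix_parse_error")
  }
  if (anyNA(num)) {
    abort(sprintf("missing cell in '%s'.", path),
          class = "ramanmix_parse_error")
  }
  num
}

#' Read a spectral library from delimited text
#'
#' Two dialects are supported. `"matrix"`: one delimited file whose first
#' column is the wavenumber axis and whose remaining columns are spectra,
#' with a single header row of labels (delimiter auto-detected among
#' comma, tab, semicolon). `"per-file"`: a directory of two-column
#' (wavenumber, intensity) files sharing one axis, read in sorted file
#' order; a header line is optional and detected per file.
#'
#' Axes are validated, never resampled: mismatched per-file axes are an
#' error, and a non-increasing axis is an error. Use [resample()]
#' explicitly if spectra live on different grids.
#'
#' @param path File (matrix dialect) or directory (per-file dialect).
#' @param dialect `"matrix"` or `"per-file"`.
#' @return A [spectral_library()].
#' @export
read_spectra <- function(path, dialect = c("matrix", "per-file")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    if (!file.exists(path)) stop_validation(sprintf("'%s' not found.", path))
    delim <- detect_delim(path)
    raw <- utils::read.table(path, sep = delim, header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             strip.white = TRUE)
    if (ncol(raw) < 2) stop_validation("matrix file needs >= 2 columns.")
    num <- parse_numeric_cells(as.matrix(raw), path)
    spectral_library(num[, 1], t(num[, -1, drop = FALSE]),
                     labels = names(raw)[-1])
  } else {
    if (!dir.exists(path)) stop_validation(sprintf("'%s' is not a directory.", path))
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0) stop_validation("no spectrum files in directory.")
    axis <- NULL
    rows <- vector("list", length(files))
    for (f in seq_along(files)) {
      s <- read_two_column(files[f])
      if (is.null(axis)) {
        axis <- s$wavenumber
      } else if (length(axis) != length(s$wavenumber) ||
                 any(abs(axis - s$wavenumber) > 1e-9 * pmax(abs(axis), 1))) {
        abort(sprintf(
          "axis of '%s' does not match the first file's axis; resample explicitly.",
          basename(files[f])), class = "ramanmix_axis_mismatch_error")
      }
      rows[[f]] <- s$intensity
    }
    spectral_library(axis, do.call(rbind, rows),
                     labels = tools::file_path_sans_ext(basename(files)))
  }
}

read_two_column <- function(path) {
  delim <- detect_delim(path)
  first <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- utils::read.table(path, sep = delim, header = has_header,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(raw) != 2) {
    stop_validation(sprintf("'%s' must have exactly two columns.", path))
  }
  num <- parse_numeric_cells(as.matrix(raw), path)
  spectrum(num[, 1], num[, 2])
}

#' Write a spectral library to a delimited file
#'
#' Writes the matrix dialect of [read_spectra()]: comma-separated, one
#' header row, first column `wavenumber`.
#'
#' @param lib A `spectral_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(lib, path) {
  out <- as_tibble(as.data.frame(unclass(lib), check.names = FALSE))
  readr::write_csv(out, path)
  invisible(path)
}

#' Linearly resample a spectrum onto a new axis
#'
#' Plain linear interpolation between neighbouring axis points.
#' Extrapolation beyond the spectrum's range is refused rather than
#' guessed at.
#'
#' @param spec A spectrum (data frame with `wavenumber`, `intensity`).
#' @param target_axis Strictly increasing wavenumbers within the
#'   spectrum's range.
#' @return A new `raman_spectrum` on `target_axis`.
#' @export
resample <- function(spec, target_axis) {
  spec <- as_spectrum(spec)
  target_axis <- as.numeric(target_axis)
  rng <- range(spec$wavenumber)
  if (any(target_axis < rng[1]) || any(target_axis > rng[2])) {
    abort("target axis extends beyond the spectrum's range; cannot extrapolate.",
          class = "ramanmix_range_error")
  }
  if (length(target_axis) > 1 && any(diff(target_axis) <= 0)) {
    stop_validation("target axis must be strictly increasing.")
  }
  y <- stats::approx(spec$wavenumber, spec$intensity, xout = target_axis,
                     method = "linear", ties = "ordered")$y
  # a single-point target is allowed here even though a full spectrum
  # needs >= 2 points, so build the tibble directly
  out <- tibble(wavenumber = target_axis, intensity = y)
  class(out) <- c("raman_spectrum", class(out))
  attr(out, "label") <- attr(spec, "label")
  out
}
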