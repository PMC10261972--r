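#' Average repeated instrument readings
#'
#' Each spectral acquisition consists of a few back-to-back repetitions that
#' are averaged into a single trace before any further processing.
#'
#' @param readings A list of equal-length numeric vectors, or a matrix with
#'   one repetition per row.
#' @return The pointwise arithmetic mean, a numeric vector.
#' @export
average_repetitions <- function(readings) {
  if (is.matrix(readings)) readings <- asplit(readings, 1)
  if (!is.list(readings) || length(readings) == 0) {
    abort("readings must be a non-empty list of vectors (or a matrix).")
  }
  len <- unique(lengths(readings))
  if (length(len) != 1) abort("All repetitions must have equal length.")
  Reduce(`+`, lapply(readings, as.numeric)) / length(readings)
}

#' Conical-conical reflectance factor from raw readings
#'
#' Converts a raw digital-number triplet (sample, white reference, dark
#' current) into reflectance by ratioing the dark-corrected sample signal to
#' the dark-corrected reference signal, scaled by the reference panel's
#' reflectance factor:
#' \deqn{CCRF = \frac{I_s - I_{dc}}{I_{wr} - I_{dc}} \times RF_{wr}.}
#' Negative values (detector noise at near-zero signal) are retained, not
#' clipped — clipping would bias very dark samples — and reported via the
#' `"n_negative"` attribute for QC.
#'
#' @param i_sample Sample reading vector.
#' @param i_white White-reference reading vector (same grid).
#' @param i_dark Dark-current reading vector (same grid).
#' @param rf_panel Panel reflectance factor: scalar or per-wavelength vector.
#'   The factory calibration of the Spectralon panel used here is nominally
#'   0.99.
#' @return Reflectance vector with attribute `n_negative`.
#' @export
compute_ccrf <- function(i_sample, i_white, i_dark, rf_panel = 0.99) {
  n <- length(i_sample)
  if (length(i_white) != n || length(i_dark) != n) {
    abort("i_sample, i_white and i_dark must share one grid.")
  }
  if (!(length(rf_panel) %in% c(1L, n))) {
    abort("rf_panel must be a scalar or a per-wavelength vector.")
  }
  denom <- i_white - i_dark
  if (any(denom == 0)) {
    abort("White reference equals dark current at some wavelength (division by zero).")
  }
  out <- (i_sample - i_dark) / denom * rf_panel
  attr(out, "n_negative") <- sum(out < 0)
  out
}

#' Pick the calibration reference nearest in time
#'
#' White-reference / dark-current pairs are taken on a roughly hourly cadence
#' during a measurement session; each sample acquisition uses the pair nearest
#' in time, with ties broken toward the earlier reference.
#'
#' @param t_sample Time of the sample acquisition (numeric or POSIXct).
#' @param refs A data frame with a `time` column (same class as `t_sample`);
#'   remaining columns (typically list-columns `i_white`, `i_dark`) are
#'   carried through.
#' @return The selected row of `refs`, as a one-row tibble.
#' @export
select_reference <- function(t_sample, refs) {
  refs <- as_tibble(refs)
  if (nrow(refs) == 0) abort("Empty reference list.")
  if (!"time" %in% names(refs)) abort("refs needs a 'time' column.")
  dt <- abs(as.numeric(refs$time) - as.numeric(t_sample))
  # ties toward the earlier reference: order by (distance, time)
  best <- order(dt, as.numeric(refs$time))[1]
  refs[best, , drop = FALSE]
}

#' Savitzky-Golay smoothing of a reflectance spectrum
#'
#' Smooths with a 25 nm Savitzky-Golay window by default (25 grid points at
#' the 1 nm step), quadratic polynomial. Edges are handled by evaluating the
#' polynomial fit of the first/last full window off-centre, so polynomials up
#' to the filter order are reproduced exactly everywhere.
#'
#' @param spectrum Numeric reflectance vector.
#' @param window_nm Window width in nm (default 25).
#' @param polyorder Polynomial degree (default 2); must be below the window
#'   length in points.
#' @param step_nm Grid step in nm used to convert `window_nm` to points.
#' @return Smoothed vector, same length.
#' @export
smooth_spectrum <- function(spectrum, window_nm = 25, polyorder = 2,
                            step_nm = 1) {
  n_pts <- round(window_nm / step_nm)
  if (n_pts %% 2 == 0) n_pts <- n_pts + 1 # window must be odd in points
  if (polyorder >= n_pts) abort("polyorder must be smaller than the window.")
  if (length(spectrum) < n_pts) {
    abort("Spectrum shorter than the smoothing window.")
  }
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = n_pts))
}

#' Smooth every record of a library
#'
#' @param lib A [spectral_library()].
#' @inheritParams smooth_spectrum
#' @return A `spectral_library` with smoothed reflectance.
#' @export
smooth_library <- function(lib, window_nm = 25, polyorder = 2) {
  stopifnot(inherits(lib, "spectral_library"))
  step <- lib$wavelength[2] - lib$wavelength[1]
  sm <- t(apply(lib$reflectance, 1, smooth_spectrum,
                window_nm = window_nm, polyorder = polyorder, step_nm = step))
  rownames(sm) <- rownames(lib$reflectance)
  spectral_library(sm, lib$meta, lib$wavelength)
}
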