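#' Two-band ratio index
#'
#' The ratio index of a spectrum for a wavelength pair is
#' \eqn{RI = R(\lambda_1)/R(\lambda_2)}. A zero denominator makes the pair
#' undefined; in the exhaustive scan such pairs are masked out.
#'
#' @param spectrum Reflectance vector (or matrix, records in rows).
#' @param wavelength Wavelength grid matching `spectrum`.
#' @param l1,l2 Numerator and denominator wavelengths (nm), on the grid.
#' @return RI value(s).
#' @examples
#' ratio_index(c(0.4, 0.8), c(500, 600), 500, 600) # 0.5
#' @export
ratio_index <- function(spectrum, wavelength, l1, l2) {
  i1 <- match(l1, wavelength)
  i2 <- match(l2, wavelength)
  if (is.na(i1) || is.na(i2)) abort("l1 and l2 must lie on the grid.")
  if (is.matrix(spectrum)) {
    denom <- spectrum[, i2]
    if (any(denom == 0)) abort("Zero reflectance in the denominator band.")
    return(spectrum[, i1] / denom)
  }
  if (spectrum[i2] == 0) abort("Zero reflectance in the denominator band.")
  spectrum[i1] / spectrum[i2]
}

#' Linear regression of a ratio index on moisture content
#'
#' Ordinary least squares of RI (response) on moisture percentage
#' (explanatory): \eqn{RI = slope \cdot Moist\% + intercept}. \eqn{R^2} is the
#' squared Pearson correlation; RMSE is the root mean squared residual with
#' an `n` denominator. A constant RI gives slope 0 and \eqn{R^2 = 0}.
#'
#' @param ri RI values, one per sample.
#' @param moist_pct Moisture content in percent (0--100), same length.
#' @return An `ri_fit` list: `slope`, `intercept`, `r2`, `rmse`, `n`, plus the
#'   data for plotting. [tidy()] and [glance()] methods are provided.
#' @export
fit_ri_on_moisture <- function(ri, moist_pct) {
  n <- length(ri)
  if (n != length(moist_pct)) abort("ri and moist_pct differ in length.")
  if (n < 3) abort("Need >= 3 samples to fit.")
  if (var(moist_pct) == 0) abort("Zero variance in moisture: fit undefined.")
  if (var(ri) == 0) {
    fit <- list(slope = 0, intercept = mean(ri), r2 = 0, rmse = 0)
  } else {
    m <- lm(ri ~ moist_pct)
    res <- ri - fitted(m)
    fit <- list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                r2 = cor(ri, moist_pct)^2,
                rmse = sqrt(mean(res^2)))
  }
  structure(c(fit, list(n = n, ri = ri, moist_pct = moist_pct)),
            class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("<ri_fit> RI = %.4g * Moist%% + %.4g  (R2 = %.3f, RMSE = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r2, x$rmse, x$n))
  invisible(x)
}

#' @export
tidy.ri_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "moist_pct"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.ri_fit <- function(x, ...) {
  tibble(r.squared = x$r2, rmse = x$rmse, nobs = x$n)
}

#' Exhaustive ratio-index scan over all wavelength pairs
#'
#' For one measurement time, computes the ratio index for every ordered
#' wavelength pair on the (optionally strided) grid, regresses it on the
#' samples' moisture percentage, and records the \eqn{R^2}, slope, intercept
#' and RMSE surfaces together with the best pair. Both triangles of the
#' surface are computed: swapping the pair maps RI to 1/RI, a nonlinear
#' transform under which \eqn{R^2} is not invariant.
#'
#' The scan is vectorised per denominator band via the correlation identity
#' \eqn{R^2 = \mathrm{cor}(RI, m)^2} and closed-form OLS, so no per-pair model
#' objects are built. Denominator bands where any sample's reflectance has
#' magnitude below `min_reflectance` are masked (`NA` in the surfaces):
#' near-zero denominators produce unstable ratios. The diagonal
#' (\eqn{\lambda_1 = \lambda_2}, RI constant at 1) carries \eqn{R^2 = 0}.
#'
#' @param lib A [spectral_library()].
#' @param masses Mass records (see [moisture_content()]) covering every sample
#'   at `time`, or a data frame already carrying `moist_pct` per
#'   `sample_id` + `measurement_time`.
#' @param time Measurement time to scan.
#' @param stride_nm Grid stride in nm (default 1 = all pairs; larger strides
#'   for cheap scans).
#' @param range_nm Wavelength range to scan within (default whole grid).
#' @param min_reflectance Denominator magnitude threshold (default 1e-4).
#' @return An `ri_scan`: `wavelength` (scanned bands), `r2`, `slope`,
#'   `intercept`, `rmse` matrices (rows = lambda1, cols = lambda2), `best`
#'   one-row tibble, `time`, `n`. Ties for the best pair break toward the
#'   lowest lambda1, then lambda2.
#' @export
scan_all_pairs <- function(lib, masses, time, stride_nm = 1,
                           range_nm = NULL, min_reflectance = 1e-4) {
  stopifnot(inherits(lib, "spectral_library"))
  check_time(time)
  keep <- lib$meta$measurement_time == time
  if (sum(keep) < 3) abort("Need >= 3 samples at the measurement time.")
  x <- lib$reflectance[keep, , drop = FALSE]
  meta <- lib$meta[keep, , drop = FALSE]

  if (!"moist_pct" %in% names(masses)) masses <- moisture_content(masses)
  mm <- dplyr::left_join(
    dplyr::select(meta, "sample_id", "measurement_time"),
    dplyr::select(as_tibble(masses), "sample_id", "measurement_time",
                  "moist_pct"),
    by = c("sample_id", "measurement_time"))
  if (any(is.na(mm$moist_pct))) {
    miss <- mm$sample_id[is.na(mm$moist_pct)]
    abort(paste0("No moisture value for sample(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  m <- mm$moist_pct
  if (var(m) == 0) abort("Zero variance in moisture at this time.")

  wl <- lib$wavelength
  if (is.null(range_nm)) range_nm <- range(wl)
  cols <- which(wl >= range_nm[1] & wl <= range_nm[2])
  cols <- cols[seq(1, length(cols), by = stride_nm)]
  wls <- wl[cols]
  x <- x[, cols, drop = FALSE]
  n <- nrow(x)
  p <- length(cols)

  mc <- m - mean(m)
  ssm <- sum(mc^2)
  bad_denom <- apply(abs(x) < min_reflectance, 2, any)

  r2 <- slope <- intercept <- rmse <- matrix(NA_real_, p, p,
                                             dimnames = list(wls, wls))
  for (j in seq_len(p)) {
    if (bad_denom[j]) next
    y <- x / x[, j]                     # RI for all lambda1 at this lambda2
    mu <- colMeans(y)
    yc <- y - rep(mu, each = n)
    ssy <- colSums(yc^2)
    sxy <- colSums(yc * mc)
    b <- sxy / ssm
    r2_j <- ifelse(ssy > 0, sxy^2 / (ssy * ssm), 0)
    r2[, j] <- r2_j
    slope[, j] <- ifelse(ssy > 0, b, 0)
    intercept[, j] <- mu - slope[, j] * mean(m)
    rmse[, j] <- sqrt(pmax(ssy * (1 - r2_j), 0) / n)
  }

  if (all(is.na(r2))) abort("All denominator bands masked; nothing to scan.")
  # ties break to the lowest lambda1, then the lowest lambda2
  mx <- max(r2, na.rm = TRUE)
  hits <- which(r2 == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i1 <- hits[1, 1]; i2 <- hits[1, 2]
  best <- tibble(
    l1 = wls[i1], l2 = wls[i2],
    slope = slope[i1, i2], intercept = intercept[i1, i2],
    r2 = r2[i1, i2], rmse = rmse[i1, i2]
  )
  structure(
    list(wavelength = wls, r2 = r2, slope = slope, intercept = intercept,
         rmse = rmse, best = best, time = time, n = n,
         stride_nm = stride_nm, masked = bad_denom),
    class = "ri_scan"
  )
}

#' @export
print.ri_scan <- function(x, ...) {
  cat(sprintf("<ri_scan> %s: %d samples, %d bands (stride %d nm)\n",
              x$time, x$n, length(x$wavelength), x$stride_nm))
  cat(sprintf("  best pair: l1 = %g nm, l2 = %g nm, R2 = %.3f, RMSE = %.3g\n",
              x$best$l1, x$best$l2, x$best$r2, x$best$rmse))
  invisible(x)
}

#' @export
tidy.ri_scan <- function(x, ...) {
  tibble(l1 = rep(x$wavelength, times = length(x$wavelength)),
         l2 = rep(x$wavelength, each = length(x$wavelength)),
         r2 = as.vector(x$r2),
         slope = as.vector(x$slope),
         rmse = as.vector(x$rmse))
}

#' @export
glance.ri_scan <- function(x, ...) {
  dplyr::mutate(x$best, time = x$time, n = x$n, .before = 1)
}

#' Rectangular summary of high-R2 regions of a scan surface
#'
#' Thresholds the \eqn{R^2} surface and reports each connected component
#' (4-neighbour connectivity on the scanned grid) as its bounding box in
#' wavelength coordinates, with its cell count and maximum \eqn{R^2}.
#'
#' @param scan An `ri_scan`.
#' @param r2_threshold Threshold on \eqn{R^2} (default 0.7).
#' @return A tibble per component: `l1_min`, `l1_max`, `l2_min`, `l2_max`,
#'   `n_cells`, `max_r2`, ordered by decreasing `max_r2`. Empty when nothing
#'   exceeds the threshold.
#' @export
surface_summary <- function(scan, r2_threshold = 0.7) {
  stopifnot(inherits(scan, "ri_scan"))
  above <- !is.na(scan$r2) & scan$r2 > r2_threshold
  comp <- label_components(above)
  if (comp$n == 0) {
    return(tibble(l1_min = numeric(), l1_max = numeric(),
                  l2_min = numeric(), l2_max = numeric(),
                  n_cells = integer(), max_r2 = numeric()))
  }
  wls <- scan$wavelength
  purrr::map_dfr(seq_len(comp$n), function(id) {
    cells <- which(comp$labels == id, arr.ind = TRUE)
    tibble(l1_min = wls[min(cells[, 1])], l1_max = wls[max(cells[, 1])],
           l2_min = wls[min(cells[, 2])], l2_max = wls[max(cells[, 2])],
           n_cells = nrow(cells),
           max_r2 = max(scan$r2[comp$labels == id]))
  }) |>
    dplyr::arrange(dplyr::desc(.data$max_r2))
}

# 4-neighbour connected components of a logical matrix, iterative BFS.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  n <- 0L
  todo <- which(mask)
  queue <- integer(length(todo))
  for (start in todo) {
    if (labels[start] != 0L) next
    n <- n + 1L
    queue[1] <- start
    labels[start] <- n
    head_i <- 1L; tail_i <- 1L
    while (head_i <= tail_i) {
      cell <- queue[head_i]; head_i <- head_i + 1L
      r <- ((cell - 1L) %% nr) + 1L
      cc <- ((cell - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1) cell - 1L, if (r < nr) cell + 1L,
                   if (cc > 1) cell - nr, if (cc < nc) cell + nr)) {
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- n
          tail_i <- tail_i + 1L
          queue[tail_i] <- nb
        }
      }
    }
  }
  list(labels = labels, n = n)
}
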