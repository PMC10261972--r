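#' Per-group mean and standard-deviation spectra
#'
#' @param lib A [spectral_library()].
#' @param by Metadata columns to group by (default species x time).
#' @return A long tibble: grouping columns, `wavelength_nm`, `mean`, `sd`
#'   (sample SD, n - 1 denominator; 0 for singleton groups) and `n`.
#' @export
group_mean_sd <- function(lib, by = c("species", "measurement_time")) {
  stopifnot(inherits(lib, "spectral_library"))
  miss <- setdiff(by, names(lib$meta))
  if (length(miss) > 0) abort(paste0("Unknown grouping keys: ",
                                     paste(miss, collapse = ", ")))
  key <- do.call(paste, c(lib$meta[by], sep = "\r"))
  if (any(table(key) < 1)) abort("Empty group.")
  groups <- split(seq_len(nrow(lib$reflectance)), key)
  purrr::map_dfr(groups, function(idx) {
    sub <- lib$reflectance[idx, , drop = FALSE]
    mu <- colMeans(sub)
    s <- if (nrow(sub) > 1) apply(sub, 2, sd) else rep(0, ncol(sub))
    dplyr::bind_cols(
      lib$meta[rep(idx[1], length(lib$wavelength)), by],
      tibble(wavelength_nm = lib$wavelength, mean = mu, sd = s,
             n = length(idx))
    )
  })
}

# Rank-sum p-value following the convention: exact distribution for group
# sizes <= `exact_max` when the data are tie-free, otherwise the normal
# approximation with tie correction. All values identical => p = 1.
rank_sum_p <- function(x, y, exact_max = 12) {
  if (length(unique(c(x, y))) == 1) return(1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Per-wavelength Wilcoxon comparison of two measurement times
#'
#' For one species, tests at every wavelength whether reflectance differs
#' between two measurement times (unpaired two-sided Wilcoxon rank-sum,
#' exact for group sizes up to 12 without ties, normal approximation with tie
#' correction otherwise). Reflectance data from drying experiments are
#' typically non-normal, hence the rank test. Maximal runs of significant
#' wavelengths are reported as contiguous regions.
#'
#' @param lib A [spectral_library()].
#' @param species One species name.
#' @param time_a,time_b The two measurement times (default fresh vs 1 week).
#' @param alpha Significance level (default 0.05, the conventional 5% level;
#'   no multiple-testing correction across wavelengths by default).
#' @param p_adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) reproduces the raw
#'   per-band testing convention.
#' @return A `significance_mask`: list with `wavelength`, `p_value`,
#'   `significant`, `alpha` and a `regions` tibble (`start_nm`, `end_nm`).
#' @export
wilcoxon_bands <- function(lib, species, time_a = "0h", time_b = "1week",
                           alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(lib, "spectral_library"))
  a <- lib$reflectance[lib$meta$species == species &
                         lib$meta$measurement_time == time_a, , drop = FALSE]
  b <- lib$reflectance[lib$meta$species == species &
                         lib$meta$measurement_time == time_b, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    abort(sprintf("Need >= 2 samples of %s at both %s and %s.",
                  species, time_a, time_b))
  }
  p <- vapply(seq_along(lib$wavelength),
              function(j) rank_sum_p(a[, j], b[, j]), numeric(1))
  p <- stats::p.adjust(p, method = p_adjust)
  sig <- p < alpha
  structure(
    list(wavelength = lib$wavelength, p_value = p, significant = sig,
         alpha = alpha, species = species, times = c(time_a, time_b),
         regions = significant_regions(sig, lib$wavelength)),
    class = "significance_mask"
  )
}

#' Contiguous significant wavelength regions
#'
#' Maximal runs of `TRUE` in a significance indicator, as `[start_nm, end_nm]`
#' intervals; together the regions cover exactly the significant wavelengths.
#'
#' @param significant Logical vector.
#' @param wavelength Matching wavelength vector (nm).
#' @return A tibble with `start_nm`, `end_nm`, `n_bands`.
#' @export
significant_regions <- function(significant, wavelength) {
  stopifnot(length(significant) == length(wavelength))
  r <- rle(as.logical(significant))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble(start_nm = wavelength[starts[keep]],
         end_nm = wavelength[ends[keep]],
         n_bands = r$lengths[keep])
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf("<significance_mask> %s, %s vs %s, alpha = %g\n",
              x$species, x$times[1], x$times[2], x$alpha))
  cat(sprintf("  %d / %d wavelengths significant in %d region(s)\n",
              sum(x$significant), length(x$significant), nrow(x$regions)))
  invisible(x)
}

#' @export
tidy.significance_mask <- function(x, ...) {
  tibble(wavelength_nm = x$wavelength, p_value = x$p_value,
         significant = x$significant)
}

#' @export
glance.significance_mask <- function(x, ...) {
  tibble(species = x$species, time_a = x$times[1], time_b = x$times[2],
         alpha = x$alpha, n_significant = sum(x$significant),
         n_regions = nrow(x$regions))
}

#' Red-edge inflection point of a spectrum
#'
#' The red-edge inflection point (REP) is the wavelength of steepest
#' reflectance rise between the red chlorophyll absorption and the NIR
#' plateau; it shifts with chlorophyll content. The default method takes the
#' maximum first derivative (central differences on the smoothed spectrum)
#' within the search window, ties broken toward the lowest wavelength. The
#' classical four-point linear interpolation method is available as an
#' alternative.
#'
#' @param spectrum Smoothed reflectance vector on `wavelength`.
#' @param wavelength Wavelength grid (nm).
#' @param window Search window in nm (default `c(680, 750)`).
#' @param method `"max_first_derivative"` (default) or `"linear_four_point"`.
#' @return The REP wavelength (nm). A spectrum flat over the window is an
#'   error (the inflection is undefined).
#' @export
compute_rep <- function(spectrum, wavelength = wavelength_grid(),
                        window = c(680, 750),
                        method = c("max_first_derivative",
                                   "linear_four_point")) {
  method <- match.arg(method)
  stopifnot(length(spectrum) == length(wavelength))
  if (method == "linear_four_point") {
    # Guyot-Baret style: interpolate where the red edge crosses the midpoint
    # of the 670/780 nm reflectances, between 700 and 740 nm
    r <- function(nm) spectrum[which.min(abs(wavelength - nm))]
    r_mid <- (r(670) + r(780)) / 2
    if (r(740) == r(700)) abort("Flat red edge: REP undefined.")
    rep_nm <- 700 + 40 * (r_mid - r(700)) / (r(740) - r(700))
    return(min(max(rep_nm, window[1]), window[2]))
  }
  idx <- which(wavelength >= window[1] & wavelength <= window[2])
  if (length(idx) < 3) abort("Search window too narrow for derivatives.")
  # central differences on interior points of the window
  inner <- idx[-c(1, length(idx))]
  deriv <- (spectrum[inner + 1] - spectrum[inner - 1]) /
    (wavelength[inner + 1] - wavelength[inner - 1])
  # one-sided at the window edges so ties can resolve to the window start
  d_lo <- (spectrum[idx[2]] - spectrum[idx[1]]) /
    (wavelength[idx[2]] - wavelength[idx[1]])
  d_hi <- (spectrum[idx[length(idx)]] - spectrum[idx[length(idx) - 1]]) /
    (wavelength[idx[length(idx)]] - wavelength[idx[length(idx) - 1]])
  dd <- c(d_lo, deriv, d_hi)
  if (max(dd) - min(dd) == 0 && max(dd) == 0) {
    abort("Flat spectrum in the search window: REP undefined.")
  }
  wavelength[idx][which.max(dd)] # which.max takes the first (lowest) maximum
}

#' REP per record of a library
#'
#' @param lib A [spectral_library()] (ideally smoothed).
#' @inheritParams compute_rep
#' @return Tibble: metadata columns plus `rep_nm`.
#' @export
rep_table <- function(lib, window = c(680, 750),
                      method = "max_first_derivative") {
  stopifnot(inherits(lib, "spectral_library"))
  reps <- apply(lib$reflectance, 1, compute_rep, wavelength = lib$wavelength,
                window = window, method = method)
  dplyr::mutate(lib$meta, rep_nm = as.numeric(reps))
}

#' Rank-sum comparison of two REP samples
#'
#' Tests whether the red-edge positions of two groups of samples (e.g. two
#' species, or the two habitat groups) differ.
#'
#' @param reps_a,reps_b Numeric vectors of REP wavelengths (>= 2 each).
#' @return Two-sided rank-sum p-value.
#' @export
rep_group_test <- function(reps_a, reps_b) {
  if (length(reps_a) < 2 || length(reps_b) < 2) {
    abort("Need >= 2 REP values per group.")
  }
  rank_sum_p(reps_a, reps_b)
}

#' Per-wavelength variance explained by a categorical factor
#'
#' At every wavelength, fits reflectance on a categorical explanatory factor
#' by least squares and reports the coefficient of determination. For a
#' one-way categorical design this is the between-group share of the total
#' sum of squares, \eqn{R^2 = SS_{between}/SS_{total}}. The habitat factor
#' uses only the eight habitat-assigned species (records with
#' `habitat_group == "excluded"` are dropped); the species factor uses all
#' records.
#'
#' @param lib A [spectral_library()].
#' @param factor `"species"` or `"habitat"`.
#' @param time Optional measurement time to restrict to (the usual analysis
#'   is per time); `NULL` pools all records present.
#' @return A tibble `wavelength_nm`, `r2`, `factor`, `measurement_time`.
#'   Wavelengths with zero total variance get `r2 = 0`.
#' @export
variance_explained <- function(lib, factor = c("species", "habitat"),
                               time = NULL) {
  stopifnot(inherits(lib, "spectral_library"))
  factor <- match.arg(factor)
  keep <- rep(TRUE, nrow(lib$reflectance))
  if (!is.null(time)) {
    check_time(time)
    keep <- keep & lib$meta$measurement_time == time
  }
  if (factor == "habitat") keep <- keep & lib$meta$habitat_group != "excluded"
  x <- lib$reflectance[keep, , drop = FALSE]
  g <- if (factor == "species") lib$meta$species[keep]
       else lib$meta$habitat_group[keep]
  if (length(unique(g)) < 2) abort("Need >= 2 factor levels.")
  n_g <- as.vector(table(factor(g)))
  means <- rowsum(x, g) / n_g          # group means per wavelength
  grand <- colMeans(x)
  ssb <- colSums(n_g * (means - rep(grand, each = nrow(means)))^2)
  sst <- colSums((x - rep(grand, each = nrow(x)))^2)
  r2 <- ifelse(sst > 0, ssb / sst, 0)
  tibble(wavelength_nm = lib$wavelength, r2 = as.numeric(r2),
         factor = factor,
         measurement_time = if (is.null(time)) "all" else time)
}
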