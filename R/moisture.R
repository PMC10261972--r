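#' Gravimetric moisture content from sample masses
#'
#' The moisture content of a sample is the water fraction of its fresh mass,
#' \deqn{Moist = (F_w - D_w) / F_w,}
#' where \eqn{F_w} is the fresh (wet) mass of the sample without its container
#' and \eqn{D_w} its dry mass. Masses are weighed in the measurement
#' container, so \eqn{F_w} is obtained by first subtracting the container
#' mass. Dry mass comes from a final weighing after complete drying and is
#' shared across the measurement times of a sample.
#'
#' @param masses A data frame with columns `total_mass_g` (sample + container),
#'   `container_mass_g` and `dry_mass_g`; any other columns (ids, times) are
#'   carried through.
#' @return The input as a tibble with `fresh_mass_g` (\eqn{F_w}),
#'   `moist_fraction` in `[0, 1)` and `moist_pct` (= 100 x fraction) appended.
#' @examples
#' moisture_content(data.frame(total_mass_g = 150, container_mass_g = 50,
#'                             dry_mass_g = 25))
#' @export
moisture_content <- function(masses) {
  masses <- as_tibble(masses)
  need <- c("total_mass_g", "container_mass_g", "dry_mass_g")
  miss <- setdiff(need, names(masses))
  if (length(miss) > 0) {
    abort(paste0("masses is missing columns: ", paste(miss, collapse = ", ")))
  }
  fw <- masses$total_mass_g - masses$container_mass_g
  dw <- masses$dry_mass_g
  if (any(fw <= 0)) abort("Fresh mass F_w = total - container must be positive.")
  if (any(dw < 0)) abort("Dry mass must be non-negative.")
  if (any(dw > fw)) {
    bad <- which(dw > fw)
    abort(paste0("Dry mass exceeds fresh mass (non-physical) in row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  dplyr::mutate(masses,
                fresh_mass_g = fw,
                moist_fraction = (fw - dw) / fw,
                moist_pct = 100 * (fw - dw) / fw)
}

#' Species-by-time moisture and mass summary
#'
#' Summarises per-sample moisture per species and measurement time: the mean
#' of per-sample moisture percentages (not the moisture of mean masses — the
#' two differ whenever masses vary, by Jensen's inequality) and the mean and
#' standard deviation of the container-free sample mass \eqn{F_w}.
#'
#' @param lib A [spectral_library()] defining which (sample, time) pairs the
#'   summary must cover, or `NULL` to summarise all of `masses`.
#' @param masses Mass records: `sample_id`, `measurement_time`,
#'   `total_mass_g`, `container_mass_g`, `dry_mass_g` (one row per sample per
#'   time).
#' @return A tibble with `species`, `measurement_time`, `moist_pct` (rounded
#'   to one decimal), `mean_mass_g`, `sd_mass_g` and `n`. Single-sample groups
#'   report `sd_mass_g = 0`.
#' @export
species_moisture_table <- function(lib, masses) {
  masses <- moisture_content(masses)
  if (!is.null(lib)) {
    stopifnot(inherits(lib, "spectral_library"))
    want <- dplyr::distinct(lib$meta, .data$sample_id, .data$species,
                            .data$measurement_time)
    got <- dplyr::left_join(want, masses,
                            by = c("sample_id", "measurement_time"))
    if (any(is.na(got$moist_fraction))) {
      miss <- got[is.na(got$moist_fraction), ]
      abort(paste0(
        "Missing mass record(s) for: ",
        paste(head(paste0(miss$sample_id, " @ ", miss$measurement_time), 5),
              collapse = "; ")))
    }
    masses <- got
  } else if (!"species" %in% names(masses)) {
    abort("masses must carry a 'species' column when lib is NULL.")
  }
  masses |>
    dplyr::group_by(.data$species, .data$measurement_time) |>
    dplyr::summarise(
      moist_pct = round(mean(.data$moist_pct), 1),
      mean_mass_g = mean(.data$fresh_mass_g),
      sd_mass_g = ifelse(dplyr::n() > 1, sd(.data$fresh_mass_g), 0),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$species, levels = sphagnum_species()),
                   factor(.data$measurement_time, levels = measurement_times()))
}

#' Published per-species mass summary of the drying experiment
#'
#' The published per-species mean sample masses (container-free), their SDs,
#' final dry masses and mean moisture percentages at each measurement time,
#' shipped with the package as a plain-text table. Useful for checking the
#' moisture arithmetic against the published values and for parameterising
#' the synthetic generator.
#'
#' Note that applying the moisture equation to *mean* masses reproduces the
#' published mean moisture only for species with low between-sample mass
#' variance (the ratio of means is not the mean of ratios); *S. cuspidatum*,
#' with the tightest relative mass spread, matches at one decimal.
#'
#' @return A tibble: `species`, `measurement_time`, `moist_pct_published`,
#'   `mean_mass_g`, `sd_mass_g`, `dry_mass_g`, `dry_sd_g`.
#' @export
published_mass_summary <- function() {
  path <- system.file("extdata", "sphagnum_mass_summary.csv",
                      package = "sphagspec", mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
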