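#' Phenomenological spectral model of a moss species
#'
#' A controllable additive/multiplicative model of a *Sphagnum* reflectance
#' spectrum, not a radiative-transfer code: a visible baseline with pigment
#' absorption wells (450, 670 nm) and a green peak (550 nm), a logistic red
#' edge rising to a NIR plateau, a gentle SWIR decline, and Gaussian liquid-
#' water absorption wells whose depths scale linearly with the sample's
#' current moisture fraction. A brightness scalar multiplies the whole
#' spectrum, so band ratios cancel it.
#'
#' @param brightness Overall multiplicative brightness in (0, 1].
#' @param vis_base Visible baseline reflectance.
#' @param green_peak Green-peak height at 550 nm.
#' @param pigment_depths Depths of the 450 and 670 nm pigment wells.
#' @param red_edge_nm Red-edge inflection wavelength (nm, in 680--750).
#' @param red_edge_slope Logistic slope scale of the red edge (nm).
#' @param nir_plateau NIR plateau reflectance.
#' @param swir_decline Total linear decline from 1300 to 2500 nm.
#' @param water_wells Data frame `center_nm`, `width_nm`, `depth` of the
#'   moisture-scaled absorption wells. Defaults to the four liquid-water
#'   features at 970, 1160, 1450 and 1940 nm.
#' @return A `species_spectral_model` list.
#' @export
species_spectral_model <- function(brightness = 0.9,
                                   vis_base = 0.06,
                                   green_peak = 0.04,
                                   pigment_depths = c(0.02, 0.025),
                                   red_edge_nm = 715,
                                   red_edge_slope = 8,
                                   nir_plateau = 0.45,
                                   swir_decline = 0.11,
                                   water_wells = default_water_wells()) {
  if (red_edge_nm < 680 || red_edge_nm > 750) {
    abort("red_edge_nm must lie in [680, 750].")
  }
  structure(
    list(brightness = brightness, vis_base = vis_base,
         green_peak = green_peak, pigment_depths = pigment_depths,
         red_edge_nm = red_edge_nm, red_edge_slope = red_edge_slope,
         nir_plateau = nir_plateau, swir_decline = swir_decline,
         water_wells = as_tibble(water_wells)),
    class = "species_spectral_model"
  )
}

#' @rdname species_spectral_model
#' @export
default_water_wells <- function() {
  tibble(center_nm = c(970, 1160, 1450, 1940),
         width_nm = c(30, 40, 50, 70),
         depth = c(0.05, 0.10, 0.26, 0.28))
}

#' Default spectral models for the nine study species
#'
#' Mesotrophic species get brighter spectra with longer red-edge positions;
#' ombrotrophic species are darker with shorter red edges, *S. cuspidatum*
#' darkest of all — the qualitative contrasts the analyses should detect.
#'
#' @param water_wells Water-well table shared by all species (see
#'   [species_spectral_model()]).
#' @return Named list of `species_spectral_model`s, one per study species.
#' @export
default_species_models <- function(water_wells = default_water_wells()) {
  pars <- tibble(
    species = sphagnum_species(),
    brightness = c(0.95, 0.90, 0.92, 0.88, 0.93, 0.85, 0.50, 0.72, 0.68),
    vis_base = c(0.065, 0.060, 0.062, 0.058, 0.064, 0.055, 0.050, 0.052, 0.054),
    green_peak = c(0.045, 0.042, 0.044, 0.038, 0.046, 0.036, 0.030, 0.034, 0.035),
    red_edge_nm = c(720, 717, 718, 710, 722, 704, 698, 702, 700),
    nir_plateau = c(0.50, 0.47, 0.48, 0.44, 0.49, 0.42, 0.36, 0.40, 0.41)
  )
  models <- purrr::pmap(pars, function(species, brightness, vis_base,
                                       green_peak, red_edge_nm, nir_plateau) {
    species_spectral_model(
      brightness = brightness, vis_base = vis_base, green_peak = green_peak,
      red_edge_nm = red_edge_nm, nir_plateau = nir_plateau,
      swir_decline = 0.22 * nir_plateau, water_wells = water_wells)
  })
  setNames(models, pars$species)
}

gaussian_well <- function(wl, center, width) {
  exp(-(wl - center)^2 / (2 * width^2))
}

# species baseline shape (no water, no bleaching), before brightness
model_shape <- function(model, wl) {
  model$vis_base +
    model$green_peak * gaussian_well(wl, 550, 25) -
    model$pigment_depths[1] * gaussian_well(wl, 450, 30) -
    model$pigment_depths[2] * gaussian_well(wl, 670, 25) +
    (model$nir_plateau - model$vis_base) /
      (1 + exp(-(wl - model$red_edge_nm) / model$red_edge_slope)) -
    model$swir_decline * pmax(wl - 1300, 0) / 1200
}

# total water absorption at moisture fraction 1
model_water_absorption <- function(model, wl) {
  w <- model$water_wells
  Reduce(`+`, purrr::pmap(w, function(center_nm, width_nm, depth) {
    depth * gaussian_well(wl, center_nm, width_nm)
  }))
}

#' Habitat-structured drying model
#'
#' Each sample's water mass decays exponentially,
#' \eqn{W(t) = W_0 e^{-r t}} (t in days), so the moisture fraction
#' \eqn{\theta(t) = W(t)/(W(t) + D_w)} is non-increasing. The per-species
#' defaults (initial moisture, e-folding rate, dry mass) are set to the
#' drying behaviour observed for the nine study species over one week:
#' ombrotrophic species hold water far longer than mesotrophic ones
#' (*S. cuspidatum* barely dries at all). Moisture loss also bleaches the
#' sample: the spectrum baseline rises by `bleach` per unit of lost moisture
#' fraction, emulating the whitening of drying moss.
#'
#' @param species_params Data frame `species`, `initial_moisture` (fraction),
#'   `decay_per_day`, `dry_mass_g`; defaults cover the nine study species.
#' @param bleach Baseline brightening per unit moisture-fraction loss
#'   (default 0.25; set 0 to disable bleaching).
#' @return A `drying_model` list.
#' @export
drying_model <- function(species_params = default_drying_params(),
                         bleach = 0.25) {
  species_params <- as_tibble(species_params)
  need <- c("species", "initial_moisture", "decay_per_day", "dry_mass_g")
  miss <- setdiff(need, names(species_params))
  if (length(miss) > 0) {
    abort(paste0("species_params missing: ", paste(miss, collapse = ", ")))
  }
  if (any(species_params$initial_moisture <= 0 |
          species_params$initial_moisture >= 1)) {
    abort("initial_moisture must lie in (0, 1).")
  }
  structure(list(species_params = species_params, bleach = bleach),
            class = "drying_model")
}

#' @rdname drying_model
#' @export
default_drying_params <- function() {
  tibble(
    species = sphagnum_species(),
    habitat_group = habitat_group(sphagnum_species()),
    initial_moisture = c(0.916, 0.871, 0.889, 0.899, 0.916,
                         0.903, 0.987, 0.926, 0.944),
    decay_per_day = c(0.169, 0.266, 0.203, 0.148, 0.174,
                      0.104, 0.024, 0.079, 0.046),
    dry_mass_g = c(43.3, 47.6, 46.2, 60.8, 48.3, 72.2, 35.1, 81.7, 88.3)
  )
}

#' Simulation configuration
#'
#' @param n_replicates Samples per species (default 10).
#' @param times Measurement times to generate (default all four).
#' @param seed Integer seed; the same seed yields a bit-identical library.
#' @param intraspecific_cv Coefficient of variation of the multiplicative
#'   between-replicate brightness variation; it also scales the jitter on
#'   per-sample initial moisture, drying rate and dry mass. 0 makes all
#'   replicates of a species identical.
#' @param noise_sd SD of additive measurement noise on reflectance.
#' @param container_mass_g Mass of the (black, painted) measurement container.
#' @param species Species subset to simulate (default all nine).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_replicates = 10,
                              times = measurement_times(),
                              seed = 1L,
                              intraspecific_cv = 0.08,
                              noise_sd = 0.002,
                              container_mass_g = 50,
                              species = sphagnum_species()) {
  stopifnot(n_replicates >= 1, length(times) >= 1)
  bad <- setdiff(times, measurement_times())
  if (length(bad) > 0) abort(paste0("Unknown times: ", paste(bad, collapse = ", ")))
  habitat_group(species) # closed-world check
  structure(
    list(n_replicates = as.integer(n_replicates), times = times,
         seed = as.integer(seed), intraspecific_cv = intraspecific_cv,
         noise_sd = noise_sd, container_mass_g = container_mass_g,
         species = species),
    class = "simulation_config"
  )
}

time_days <- function(times) {
  c("0h" = 0, "24h" = 1, "48h" = 2, "1week" = 7)[times]
}

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic drying spectral library
#'
#' Emulates the study design: `n_replicates` samples of each species measured
#' at each time while drying. Reflectance is the species baseline with
#' moisture-scaled water-absorption wells and bleaching, a per-sample
#' multiplicative lognormal brightness factor, and additive measurement
#' noise. Masses are generated consistently with the moisture trajectory, so
#' applying the gravimetric moisture equation to the generated masses
#' recovers the planted moisture fractions exactly.
#'
#' @param config A [simulation_config()].
#' @param models Named list of [species_spectral_model()]s covering
#'   `config$species`.
#' @param drying A [drying_model()] covering `config$species`.
#' @param grid Wavelength grid.
#' @return A list: `library` (a [spectral_library()]), `masses` (tibble in
#'   the mass-records layout) and `truth` (planted per-record moisture and
#'   generator parameters; see [planted_truth()]).
#' @examples
#' sim <- generate_library(simulation_config(n_replicates = 2, seed = 7))
#' sim$library
#' @export
generate_library <- function(config = simulation_config(),
                             models = default_species_models(),
                             drying = drying_model(),
                             grid = wavelength_grid()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(drying, "drying_model"))
  miss <- setdiff(config$species, names(models))
  if (length(miss) > 0) {
    abort(paste0("No spectral model for: ", paste(miss, collapse = ", ")))
  }
  miss_d <- setdiff(config$species, drying$species_params$species)
  if (length(miss_d) > 0) {
    abort(paste0("No drying parameters for: ", paste(miss_d, collapse = ", ")))
  }
  cv <- config$intraspecific_cv
  days <- time_days(config$times)
  n_rep <- config$n_replicates

  res <- purrr::imap(setNames(seq_along(config$species), config$species),
                     function(i_sp, sp) {
    model <- models[[sp]]
    dp <- drying$species_params[drying$species_params$species == sp, ]
    shape <- model_shape(model, grid)
    absorb <- model_water_absorption(model, grid)
    # per-species sub-stream off the one global seed
    with_local_seed(config$seed + 7919L * i_sp, {
      rows <- list(); meta <- list(); masses <- list(); truth <- list()
      for (r in seq_len(n_rep)) {
        sample_id <- sprintf("%s_%02d", sp, r)
        bright <- model$brightness * exp(rnorm(1, 0, cv))
        # jitter initial moisture on the log-odds scale so the spread scales
        # with how far the species sits from full saturation
        lo <- log(dp$initial_moisture / (1 - dp$initial_moisture)) +
          rnorm(1, 0, 2 * cv)
        theta0 <- min(max(1 / (1 + exp(-lo)), 0.3), 0.998)
        rate <- dp$decay_per_day * exp(rnorm(1, 0, 2 * cv))
        d_w <- dp$dry_mass_g * exp(rnorm(1, 0, 2 * cv))
        w0 <- d_w * theta0 / (1 - theta0)
        noise <- matrix(rnorm(length(config$times) * length(grid),
                              0, config$noise_sd),
                        nrow = length(config$times))
        for (ti in seq_along(config$times)) {
          tm <- config$times[ti]
          w_t <- w0 * exp(-rate * days[ti])
          theta <- w_t / (w_t + d_w)
          refl <- bright *
            (shape + drying$bleach * (theta0 - theta) - theta * absorb) +
            (if (config$noise_sd > 0) noise[ti, ] else 0)
          if (any(refl <= 0 | refl >= 1)) {
            abort(sprintf(
              "Spectral model for %s at %s leaves (0, 1): range [%.3f, %.3f].",
              sp, tm, min(refl), max(refl)))
          }
          rid <- sprintf("%s_%s", sample_id, tm)
          rows[[rid]] <- refl
          meta[[rid]] <- tibble(
            record_id = rid, sample_id = sample_id, species = sp,
            habitat_group = habitat_group(sp),
            nutrient_level = NA_character_, site = "synthetic",
            measurement_time = tm)
          masses[[rid]] <- tibble(
            sample_id = sample_id, measurement_time = tm,
            total_mass_g = w_t + d_w + config$container_mass_g,
            container_mass_g = config$container_mass_g, dry_mass_g = d_w)
          truth[[rid]] <- tibble(
            record_id = rid, sample_id = sample_id, species = sp,
            habitat_group = habitat_group(sp), measurement_time = tm,
            moist_fraction = theta, water_mass_g = w_t, dry_mass_g = d_w,
            initial_moisture = theta0, decay_per_day = rate,
            brightness = bright)
        }
      }
      list(refl = do.call(rbind, rows),
           meta = dplyr::bind_rows(meta),
           masses = dplyr::bind_rows(masses),
           truth = dplyr::bind_rows(truth))
    })
  })

  refl <- do.call(rbind, purrr::map(res, "refl"))
  meta <- dplyr::bind_rows(purrr::map(res, "meta"))
  rownames(refl) <- meta$record_id
  truth <- dplyr::bind_rows(purrr::map(res, "truth"))
  attr(truth, "water_wells") <- models[[config$species[1]]]$water_wells
  attr(truth, "habitat_partition") <-
    setNames(habitat_group(config$species), config$species)
  list(
    library = spectral_library(refl, meta, grid),
    masses = dplyr::bind_rows(purrr::map(res, "masses")),
    truth = truth
  )
}

#' Planted ground truth of a synthetic library
#'
#' Regenerates the simulation deterministically and returns only the
#' generating parameters: per-record true moisture fractions, water/dry
#' masses, per-sample brightness, the water-well centres and the habitat
#' partition — the quantities recovery tests compare against.
#'
#' @inheritParams generate_library
#' @return A tibble of per-record truth with attributes `water_wells` and
#'   `habitat_partition`.
#' @export
planted_truth <- function(config = simulation_config(),
                          models = default_species_models(),
                          drying = drying_model(),
                          grid = wavelength_grid()) {
  generate_library(config, models, drying, grid)$truth
}
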