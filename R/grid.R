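#' Canonical wavelength grid
#'
#' Spectral libraries in this package live on a single shared wavelength grid.
#' The field-spectroradiometer range used throughout is 350--2500 nm at a 1 nm
#' step (2151 points); the defaults encode that convention.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm).
#' @param step_nm Grid increment (nm).
#'
#' @return A numeric vector of wavelengths, strictly increasing.
#' @examples
#' g <- wavelength_grid()
#' length(g) # 2151
#' @export
wavelength_grid <- function(start_nm = 350, end_nm = 2500, step_nm = 1) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || !is.numeric(step_nm) ||
      step_nm <= 0 || end_nm <= start_nm) {
    abort("Invalid grid: need start_nm < end_nm and step_nm > 0.")
  }
  seq(start_nm, end_nm, by = step_nm)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2 || any(diff(grid) <= 0)) {
    abort("Wavelength grid must be numeric and strictly increasing.")
  }
  invisible(grid)
}

# Closed-world species sets -------------------------------------------------

#' Study species and the habitat partition
#'
#' The nine study species and the deterministic two-group habitat partition
#' used for habitat-level analyses. The mesotrophic group holds the species of
#' richer minerotrophic sites (plus the intermediate *S. fallax*); the
#' oligo-ombrotrophic group holds the bog species (plus the oligotrophic
#' *S. angustifolium*). *S. capillifolium*, collected from peatland-edge
#' ecotones, stays outside the division and is labelled `"excluded"`.
#'
#' @return `sphagnum_species()` returns the nine species names.
#' @examples
#' habitat_group(c("fallax", "fuscum", "capillifolium"))
#' @export
sphagnum_species <- function() {
  c("centrale", "girgensohnii", "riparium", "capillifolium", "fallax",
    "angustifolium", "cuspidatum", "fuscum", "rubellum")
}

.habitat_map <- c(
  centrale      = "mesotrophic",
  girgensohnii  = "mesotrophic",
  riparium      = "mesotrophic",
  fallax        = "mesotrophic",
  angustifolium = "oligo-ombrotrophic",
  cuspidatum    = "oligo-ombrotrophic",
  fuscum        = "oligo-ombrotrophic",
  rubellum      = "oligo-ombrotrophic",
  capillifolium = "excluded"
)

#' @rdname sphagnum_species
#' @param species Character vector of species epithets (e.g. `"fallax"`).
#'   Unknown species are an error: the habitat map is closed-world.
#' @return `habitat_group()` returns the matching habitat labels.
#' @export
habitat_group <- function(species) {
  species <- as.character(species)
  unknown <- setdiff(unique(species), names(.habitat_map))
  if (length(unknown) > 0) {
    abort(paste0("Unknown species (no habitat assignment): ",
                 paste(unknown, collapse = ", ")))
  }
  unname(.habitat_map[species])
}

#' @rdname sphagnum_species
#' @export
measurement_times <- function() c("0h", "24h", "48h", "1week")

check_time <- function(time) {
  if (length(time) != 1 || !time %in% measurement_times()) {
    abort(paste0("measurement_time must be one of: ",
                 paste(measurement_times(), collapse = ", ")))
  }
  time
}
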