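#' Read a spectral library from its two-file CSV layout
#'
#' A library on disk is a pair of UTF-8 CSVs: a wide spectra file whose first
#' column `wavelength_nm` holds the grid and whose remaining columns are one
#' reflectance trace per record id, and a metadata file keyed by `record_id`
#' (or by `sample_id` + `measurement_time`, from which the record id is
#' formed). Deposited libraries with different column names are handled with
#' `col_map`.
#'
#' @param path Path to the wide spectra CSV.
#' @param metadata_path Path to the metadata CSV.
#' @param col_map Optional named character vector mapping canonical metadata
#'   column names (names of the vector) to the file's column names (values),
#'   e.g. `c(species = "Species", sample_id = "ID")`.
#'
#' @return A [spectral_library()]. Spectral records lacking a metadata row (or
#'   vice versa) are an error listing the orphan ids; a non-monotone
#'   wavelength column is an error.
#' @export
read_spectral_library <- function(path, metadata_path, col_map = NULL) {
  if (!file.exists(path)) abort(paste0("No such spectra file: ", path))
  if (!file.exists(metadata_path)) {
    abort(paste0("No such metadata file: ", metadata_path))
  }
  spec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          comment = "#")
  if (!"wavelength_nm" %in% names(spec)) {
    abort("Spectra file must have a 'wavelength_nm' column.")
  }
  wl <- spec$wavelength_nm
  if (!is.numeric(wl)) abort("wavelength_nm column does not parse numerically.")
  if (length(wl) < 2 || any(diff(wl) <= 0)) {
    abort("wavelength_nm column is not strictly increasing.")
  }
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE,
                          progress = FALSE, comment = "#")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(meta)) {
        names(meta)[names(meta) == col_map[[canon]]] <- canon
      }
    }
  }
  if (!"record_id" %in% names(meta)) {
    if (all(c("sample_id", "measurement_time") %in% names(meta))) {
      meta$record_id <- paste(meta$sample_id, meta$measurement_time, sep = "_")
    } else {
      abort("Metadata needs 'record_id' or 'sample_id' + 'measurement_time'.")
    }
  }
  if (anyDuplicated(meta$record_id)) {
    dup <- unique(meta$record_id[duplicated(meta$record_id)])
    abort(paste0("Duplicated (sample_id, measurement_time) metadata rows: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  ids <- setdiff(names(spec), "wavelength_nm")
  refl <- t(as.matrix(spec[ids]))
  rownames(refl) <- ids
  orphans <- setdiff(ids, meta$record_id)
  if (length(orphans) > 0) {
    abort(paste0("Spectral records without metadata: ",
                 paste(head(orphans, 10), collapse = ", ")))
  }
  meta <- meta[match(ids, meta$record_id), , drop = FALSE]
  spectral_library(refl, meta, wl)
}

#' Write a spectral library to the two-file CSV layout
#'
#' Inverse of [read_spectral_library()]: a write/read round-trip reproduces
#' reflectance values to better than 1e-9 relative error.
#'
#' @param lib A [spectral_library()].
#' @param path Output path for the wide spectra CSV.
#' @param metadata_path Output path for the metadata CSV.
#' @return Invisibly, `c(path, metadata_path)`.
#' @export
write_spectral_library <- function(lib, path, metadata_path) {
  stopifnot(inherits(lib, "spectral_library"))
  out <- tibble(wavelength_nm = lib$wavelength)
  if (nrow(lib$reflectance) > 0) {
    mat <- as.data.frame(t(lib$reflectance))
    names(mat) <- lib$meta$record_id
    out <- dplyr::bind_cols(out, mat)
  }
  readr::write_csv(out, path, progress = FALSE)
  readr::write_csv(lib$meta, metadata_path, progress = FALSE)
  invisible(c(path, metadata_path))
}

#' Resample a spectrum onto the canonical grid
#'
#' Linear interpolation of instrument-native bands onto a target grid; exact
#' where input nodes coincide with grid nodes. Extrapolation is refused.
#'
#' @param wavelengths Strictly increasing input wavelengths (nm).
#' @param values Values at `wavelengths`.
#' @param grid Target grid, e.g. [wavelength_grid()].
#' @return Numeric vector of `length(grid)`.
#' @examples
#' resample_to_grid(c(400, 402, 404), c(0.1, 0.2, 0.3), c(400, 401, 402))
#' @export
resample_to_grid <- function(wavelengths, values, grid = wavelength_grid()) {
  check_grid(grid)
  if (length(wavelengths) != length(values)) {
    abort("wavelengths and values differ in length.")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("Input wavelengths must be strictly increasing.")
  }
  if (min(grid) < min(wavelengths) || max(grid) > max(wavelengths)) {
    abort("Grid extends beyond the input wavelength range; no extrapolation.")
  }
  approx(wavelengths, values, xout = grid, method = "linear")$y
}
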