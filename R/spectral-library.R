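#' Spectral library container
#'
#' A `spectral_library` couples a reflectance matrix (records in rows,
#' wavelengths in columns) with a metadata tibble, one row per record, on a
#' shared wavelength grid. Record ids follow the
#' `"<species>_<replicate 01..n>_<time>"` convention and key the join between
#' the two tables.
#'
#' @param reflectance Numeric matrix, one row per record, `length(wavelength)`
#'   columns. Row names are record ids.
#' @param meta Data frame with at least `record_id`, `sample_id`, `species`,
#'   `measurement_time`; `habitat_group` is derived from `species` when absent.
#' @param wavelength Numeric wavelength grid (nm), strictly increasing.
#'
#' @return An object of class `spectral_library`.
#' @seealso [read_spectral_library()], [generate_library()]
#' @export
spectral_library <- function(reflectance, meta, wavelength = wavelength_grid()) {
  check_grid(wavelength)
  reflectance <- as.matrix(reflectance)
  meta <- as_tibble(meta)
  if (ncol(reflectance) != length(wavelength)) {
    abort(sprintf("reflectance has %d columns but the grid has %d wavelengths.",
                  ncol(reflectance), length(wavelength)))
  }
  need <- c("record_id", "sample_id", "species", "measurement_time")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(paste0("meta is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(meta$record_id)) {
    dup <- unique(meta$record_id[duplicated(meta$record_id)])
    abort(paste0("Duplicated record ids in metadata: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (nrow(reflectance) != nrow(meta)) {
    abort(sprintf("reflectance has %d records but meta has %d rows.",
                  nrow(reflectance), nrow(meta)))
  }
  if (is.null(rownames(reflectance))) rownames(reflectance) <- meta$record_id
  if (!identical(rownames(reflectance), as.character(meta$record_id))) {
    # align by id; any orphan is an error
    orphan <- setdiff(rownames(reflectance), meta$record_id)
    if (length(orphan) > 0) {
      abort(paste0("Spectral records without metadata: ",
                   paste(head(orphan, 5), collapse = ", ")))
    }
    orphan_meta <- setdiff(meta$record_id, rownames(reflectance))
    if (length(orphan_meta) > 0) {
      abort(paste0("Metadata rows without spectra: ",
                   paste(head(orphan_meta, 5), collapse = ", ")))
    }
    reflectance <- reflectance[as.character(meta$record_id), , drop = FALSE]
  }
  bad_time <- setdiff(unique(meta$measurement_time), measurement_times())
  if (length(bad_time) > 0) {
    abort(paste0("Unknown measurement_time label(s): ",
                 paste(bad_time, collapse = ", ")))
  }
  if (!"habitat_group" %in% names(meta)) {
    meta$habitat_group <- habitat_group(meta$species)
  } else {
    habitat_group(meta$species) # validates species are known
  }
  structure(
    list(wavelength = as.numeric(wavelength),
         reflectance = reflectance,
         meta = meta),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf(
    "<spectral_library> %d records x %d wavelengths (%g-%g nm)\n",
    nrow(x$reflectance), length(x$wavelength),
    min(x$wavelength), max(x$wavelength)))
  cat(sprintf("  species: %s\n",
              paste(sort(unique(x$meta$species)), collapse = ", ")))
  cat(sprintf("  times:   %s\n",
              paste(intersect(measurement_times(),
                              unique(x$meta$measurement_time)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.spectral_library <- function(x) dim(x$reflectance)

#' Long tabular view of a spectral library
#'
#' @param x A [spectral_library()].
#' @param ... Unused.
#' @return A tibble with one row per record x wavelength: the metadata columns,
#'   `wavelength_nm` and `reflectance`.
#' @export
as_tibble.spectral_library <- function(x, ...) {
  long <- tibble(
    record_id = rep(x$meta$record_id, each = length(x$wavelength)),
    wavelength_nm = rep(x$wavelength, times = nrow(x$reflectance)),
    reflectance = as.vector(t(x$reflectance))
  )
  dplyr::left_join(long, x$meta, by = "record_id") |>
    dplyr::relocate("wavelength_nm", "reflectance", .after = dplyr::last_col())
}

#' @export
tidy.spectral_library <- function(x, ...) as_tibble(x)

#' Subset a spectral library by metadata predicate
#'
#' `filter_library()` keeps the records whose metadata rows satisfy the
#' dplyr-style conditions, preserving the grid.
#'
#' @param lib A [spectral_library()].
#' @param ... Conditions on metadata columns, as in [dplyr::filter()].
#' @return A `spectral_library` with the matching records.
#' @examples
#' \dontrun{
#' filter_library(lib, species == "fuscum", measurement_time == "0h")
#' }
#' @export
filter_library <- function(lib, ...) {
  stopifnot(inherits(lib, "spectral_library"))
  keep <- dplyr::filter(dplyr::mutate(lib$meta, .row = dplyr::row_number()), ...)
  spectral_library(lib$reflectance[keep$.row, , drop = FALSE],
                   dplyr::select(keep, -".row"), lib$wavelength)
}
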