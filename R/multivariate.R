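#' PCA of a spectral library at one measurement time
#'
#' Principal component analysis of the reflectance spectra of one measurement
#' time, after centering and (by default) scaling each wavelength to unit
#' variance. Dimensionality reduction ahead of clustering avoids the strong
#' multicollinearity of adjacent bands. Component signs follow a fixed
#' convention — the largest-magnitude loading of each component is positive —
#' so score plots are reproducible across record orderings and platforms.
#'
#' @param lib A [spectral_library()].
#' @param time Measurement time to analyse (`NULL` pools all records).
#' @param scale_unit Scale each wavelength to unit variance (default `TRUE`).
#'   Constant wavelengths are left unscaled (divisor 1).
#' @return A `spectra_pca`: `rotation` (loadings), `scores` tibble with the
#'   record metadata, `explained_fraction`, `sdev`, `center`, `scale`.
#' @export
run_pca <- function(lib, time = NULL, scale_unit = TRUE) {
  stopifnot(inherits(lib, "spectral_library"))
  keep <- rep(TRUE, nrow(lib$reflectance))
  if (!is.null(time)) {
    check_time(time)
    keep <- lib$meta$measurement_time == time
  }
  x <- lib$reflectance[keep, , drop = FALSE]
  meta <- lib$meta[keep, , drop = FALSE]
  if (nrow(x) < 2) abort("Need >= 2 samples for PCA.")
  scl <- FALSE
  if (scale_unit) {
    s <- apply(x, 2, sd)
    scl <- ifelse(s > 0, s, 1)
  }
  p <- prcomp(x, center = TRUE, scale. = scl)
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i_max <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i_max, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  expl <- p$sdev^2 / sum(p$sdev^2)
  scores <- dplyr::bind_cols(
    meta,
    as_tibble(p$x, .name_repair = "minimal")
  )
  structure(
    list(rotation = p$rotation, scores = scores,
         explained_fraction = expl, sdev = p$sdev,
         center = p$center, scale = p$scale,
         wavelength = lib$wavelength,
         time = if (is.null(time)) "all" else time),
    class = "spectra_pca"
  )
}

#' @export
print.spectra_pca <- function(x, ...) {
  k <- min(3, length(x$explained_fraction))
  cat(sprintf(
    "<spectra_pca> %s: %d records, PC1-PC%d explain %.1f%% of variance\n",
    x$time, nrow(x$scores), k, 100 * sum(x$explained_fraction[seq_len(k)])))
  invisible(x)
}

#' @export
tidy.spectra_pca <- function(x, ...) {
  tibble(component = seq_along(x$explained_fraction),
         sdev = x$sdev,
         explained_fraction = x$explained_fraction,
         cumulative = cumsum(x$explained_fraction))
}

#' @export
glance.spectra_pca <- function(x, ...) {
  tibble(time = x$time, n = nrow(x$scores),
         n_components = length(x$explained_fraction),
         explained_pc1_3 = sum(x$explained_fraction[seq_len(
           min(3, length(x$explained_fraction)))]))
}

#' Ward hierarchical clustering on leading principal components
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' samples in the space of the first `n_pc` principal-component scores, with
#' cluster labels from cutting the dendrogram at `k` clusters. The defaults
#' (`n_pc = 3`, `k = 3`) reflect that three components typically capture the
#' bulk (>90%) of spectral variance in this kind of library.
#'
#' @param pca A `spectra_pca` from [run_pca()].
#' @param n_pc Number of leading components to cluster on.
#' @param k Number of clusters to cut at.
#' @param linkage `"ward.D2"` (Ward on Euclidean distances, default),
#'   `"complete"` or `"average"`.
#' @return A `spectra_hclust`: the `hclust` tree, a `labels` tibble (record
#'   metadata + `cluster`), `k`, `n_pc`.
#' @export
hierarchical_cluster <- function(pca, n_pc = 3, k = 3, linkage = "ward.D2") {
  stopifnot(inherits(pca, "spectra_pca"))
  n <- nrow(pca$scores)
  avail <- length(pca$explained_fraction)
  if (n_pc > avail) abort(sprintf("Only %d components available.", avail))
  if (k > n) abort("k cannot exceed the number of samples.")
  sc <- as.matrix(pca$scores[paste0("PC", seq_len(n_pc))])
  tree <- hclust(dist(sc, method = "euclidean"), method = linkage)
  cl <- cutree(tree, k = k)
  structure(
    list(tree = tree,
         labels = dplyr::mutate(pca$scores, cluster = as.integer(cl)),
         k = k, n_pc = n_pc, linkage = linkage, time = pca$time),
    class = "spectra_hclust"
  )
}

#' @export
print.spectra_hclust <- function(x, ...) {
  cat(sprintf("<spectra_hclust> %s: %d samples, %s linkage on %d PCs, k = %d\n",
              x$time, nrow(x$labels), x$linkage, x$n_pc, x$k))
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' @export
tidy.spectra_hclust <- function(x, ...) x$labels

#' Cluster composition against species and habitat
#'
#' Cross-tabulates cluster labels with a metadata grouping and reports each
#' cluster's majority-group purity. For habitat purity, records outside the
#' habitat division (`"excluded"`) are dropped before computing shares.
#'
#' @param clust A `spectra_hclust` (or a vector of cluster labels).
#' @param meta Metadata tibble aligned with the labels (taken from `clust`
#'   when it is a `spectra_hclust`).
#' @param group Metadata column to tabulate (default `"habitat_group"`).
#' @return A tibble per cluster: `n`, counts per group level (wide), the
#'   majority group and `purity` in `[0, 1]`.
#' @export
cluster_composition <- function(clust, meta = NULL, group = "habitat_group") {
  if (inherits(clust, "spectra_hclust")) {
    meta <- clust$labels
    labels <- clust$labels$cluster
  } else {
    labels <- as.integer(clust)
    if (is.null(meta)) abort("meta required when clust is a plain label vector.")
    if (length(labels) != nrow(meta)) abort("labels and meta lengths differ.")
    meta <- dplyr::mutate(as_tibble(meta), cluster = labels)
  }
  if (!group %in% names(meta)) abort(paste0("No metadata column ", group))
  tab <- meta |>
    dplyr::count(.data$cluster, value = .data[[group]]) |>
    tidyr::pivot_wider(names_from = "value", values_from = "n",
                       values_fill = 0L)
  counted <- setdiff(names(tab), c("cluster", "excluded"))
  purity <- apply(tab[counted], 1, function(r) {
    if (sum(r) == 0) return(NA_real_)
    max(r) / sum(r)
  })
  majority <- counted[apply(tab[counted], 1, which.max)]
  dplyr::mutate(tab,
                n = as.integer(rowSums(tab[setdiff(names(tab), "cluster")])),
                majority = majority, purity = as.numeric(purity)) |>
    dplyr::relocate("n", .after = "cluster")
}
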