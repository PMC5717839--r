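#' Configuration of the luminal-fraction pipeline
#'
#' Lumina are extracted by k-means clustering of the CIELAB chroma
#' channels (A, B), selection of the near-white cluster(s), morphological
#' closing, and discarding connected components outside a size window.
#'
#' @param k number of colour clusters (default 6).
#' @param selected_clusters `"auto"` (select clusters whose Lab centre has
#'   L > 85 and chroma < 20, i.e. near-white) or an integer vector of
#'   cluster indices.
#' @param closing_radius_px disk radius for morphological closing
#'   (0 disables).
#' @param min_region_px,max_region_px connected-component size window in
#'   pixels; components outside it are discarded.
#' @param grid_px grid cell side for the luminal-fraction map. Defaults to
#'   500 px so lambda maps share the cellularity-map geometry; the finer
#'   20 px grid is available by configuration.
#' @param complement_clusters indices of clusters that identify the
#'   *exterior* of lumina; their union is complemented before use.
#' @return object of class `lumen_config`.
#' @export
lumen_config <- function(k = 6L, selected_clusters = "auto",
                         closing_radius_px = 5L, min_region_px = 50L,
                         max_region_px = 1e7, grid_px = 500L,
                         complement_clusters = integer(0)) {
  stopifnot(k >= 2, closing_radius_px >= 0, min_region_px > 0,
            max_region_px > min_region_px, grid_px >= 1)
  structure(list(k = as.integer(k), selected_clusters = selected_clusters,
                 closing_radius_px = as.integer(closing_radius_px),
                 min_region_px = min_region_px,
                 max_region_px = max_region_px,
                 grid_px = as.integer(grid_px),
                 complement_clusters = complement_clusters),
            class = "lumen_config")
}

#' K-means colour clustering in the CIELAB chroma plane
#'
#' Clusters pixels on the (A, B) channels of the Lab representation.
#' For large images the cluster centres are estimated on a random sample
#' of pixels (multiple restarts, lowest within-cluster sum of squares)
#' and every pixel is then assigned to its nearest centre. If the image
#' holds fewer distinct colours than `k`, `k` is reduced with a warning.
#'
#' @param image RGB array (rows x cols x 3).
#' @param k number of clusters.
#' @param seed integer seed for the sampling and k-means restarts.
#' @param max_sample maximum number of pixels used to fit the centres.
#' @return object of class `color_clusters`: `labels` (integer matrix),
#'   `centers_ab` (k x 2), `centers_L` (mean lightness per cluster),
#'   `sizes`, `k`.
#' @export
cluster_colors <- function(image, k = 6L, seed = NULL, max_sample = 2e5) {
  lab <- rgb_to_lab(image)
  ab <- cbind(as.vector(lab$a), as.vector(lab$b))
  with_seed(seed, {
    n <- nrow(ab)
    idx <- if (n > max_sample) sample.int(n, max_sample) else seq_len(n)
    distinct <- unique(round(ab[idx, , drop = FALSE], 6))
    k_eff <- min(k, nrow(distinct))
    if (k_eff < k) {
      warning("only ", nrow(distinct), " distinct colours; reducing k to ",
              k_eff)
    }
    if (k_eff == 1L) {
      labels <- matrix(1L, nrow(lab$L), ncol(lab$L))
      centers <- matrix(colMeans(ab), 1, 2)
    } else {
      km <- kmeans(ab[idx, , drop = FALSE], centers = k_eff, nstart = 5,
                   iter.max = 50)
      centers <- km$centers
      # assign all pixels to nearest centre
      d_best <- rep(Inf, n); lab_best <- integer(n)
      for (j in seq_len(k_eff)) {
        d <- (ab[, 1] - centers[j, 1])^2 + (ab[, 2] - centers[j, 2])^2
        upd <- d < d_best
        d_best[upd] <- d[upd]; lab_best[upd] <- j
      }
      labels <- matrix(lab_best, nrow(lab$L), ncol(lab$L))
    }
    Lv <- as.vector(lab$L)
    centers_L <- vapply(seq_len(nrow(centers)),
                        function(j) mean(Lv[labels == j]), numeric(1))
    structure(list(labels = labels, centers_ab = unname(centers),
                   centers_L = centers_L,
                   sizes = tabulate(labels, nbins = nrow(centers)),
                   k = nrow(centers)),
              class = "color_clusters")
  })
}

#' @export
print.color_clusters <- function(x, ...) {
  cat(sprintf("<color_clusters> k = %d\n", x$k))
  for (j in seq_len(x$k)) {
    cat(sprintf("  cluster %d: L = %.1f, (a, b) = (%.1f, %.1f), %d px\n",
                j, x$centers_L[j], x$centers_ab[j, 1], x$centers_ab[j, 2],
                x$sizes[j]))
  }
  invisible(x)
}

#' Extract the lumen mask from colour clusters
#'
#' Takes the union of the selected clusters (plus the complement of any
#' clusters flagged as identifying the lumen exterior), applies
#' morphological closing with a disk structuring element, labels
#' connected components (8-connectivity) and removes components outside
#' the configured size window.
#'
#' @param clusters a [color_clusters()] result.
#' @param cfg a [lumen_config()].
#' @return logical lumen mask.
#' @export
extract_lumen_mask <- function(clusters, cfg = lumen_config()) {
  stopifnot(inherits(clusters, "color_clusters"),
            inherits(cfg, "lumen_config"))
  sel <- cfg$selected_clusters
  if (identical(sel, "auto")) {
    chroma <- sqrt(rowSums(clusters$centers_ab^2))
    sel <- which(clusters$centers_L > 85 & chroma < 20)
    if (length(sel) == 0) {
      stop("auto cluster selection found no near-white cluster ",
           "(need centre L > 85, chroma < 20); specify indices explicitly")
    }
  }
  comp <- cfg$complement_clusters
  if (length(sel) == 0 && length(comp) == 0) {
    stop("empty cluster selection")
  }
  if (any(c(sel, comp) < 1) || any(c(sel, comp) > clusters$k)) {
    stop("cluster indices out of range 1..", clusters$k)
  }
  mask <- matrix(FALSE, nrow(clusters$labels), ncol(clusters$labels))
  if (length(sel)) mask <- mask | (clusters$labels %in% sel)
  if (length(comp)) mask <- mask | !(clusters$labels %in% comp)
  filter_regions(mask, cfg$closing_radius_px, cfg$min_region_px,
                 cfg$max_region_px)
}

# closing + connected-component size filtering, shared with tests
filter_regions <- function(mask, closing_radius_px, min_region_px,
                           max_region_px) {
  m <- mask * 1
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                shape = "disc")
    m <- EBImage::closing(m, brush)
  }
  labels <- EBImage::bwlabel(m)
  n_comp <- max(labels)
  if (n_comp == 0) return(matrix(FALSE, nrow(mask), ncol(mask)))
  sizes <- tabulate(labels[labels > 0], nbins = n_comp)
  keep <- which(sizes >= min_region_px & sizes <= max_region_px)
  out <- matrix(labels %in% keep, nrow(mask), ncol(mask))
  out
}

#' Luminal-fraction map from a lumen mask
#'
#' Tiles the mask into square grid cells and reports, per cell, the
#' percentage of pixels identified as luminal space. Partial cells at the
#' image edges are dropped.
#'
#' @param mask logical lumen mask.
#' @param grid_px grid cell side length in pixels.
#' @param pixel_size_um physical pixel size (um).
#' @return a [quant_map()] of luminal fraction (%).
#' @export
luminal_fraction_map <- function(mask, grid_px = 500L, pixel_size_um = 0.23) {
  stopifnot(is.matrix(mask), grid_px >= 1)
  if (grid_px > min(dim(mask))) stop("grid larger than image")
  frac <- block_reduce(mask * 1, grid_px, stat = "mean")
  quant_map(100 * frac, grid_px, pixel_size_um,
            quantity = "luminal_fraction")
}
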