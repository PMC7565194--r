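#' Gaussian density map of cell centroids
#'
#' Kernel density on a downsampled grid. Each point contributes a
#' truncated Gaussian kernel renormalized to unit mass over the grid
#' (including at borders), so the map always sums exactly to the number
#' of points.
#'
#' @param centroids n x 2 matrix of 1-based (row, col) positions.
#' @param shape full-resolution image shape.
#' @param bandwidth_px kernel sigma in full-resolution pixels.
#' @param downsample integer grid reduction factor.
#' @return list: `map` (grid matrix), `bandwidth_px`, `downsample`,
#'   `total_count`.
#' @export
density_map <- function(centroids, shape, bandwidth_px = 20, downsample = 4L) {
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  if (nrow(centroids) && (any(centroids[, 1] < 0.5) || any(centroids[, 2] < 0.5) ||
      any(centroids[, 1] > shape[1] + 0.5) || any(centroids[, 2] > shape[2] + 0.5)))
    stop_input("centroid outside image bounds")
  if (bandwidth_px <= 0) stop_param("bandwidth must be positive")
  d <- as.integer(downsample)
  gr <- ceiling(shape[1] / d); gc <- ceiling(shape[2] / d)
  map <- matrix(0, gr, gc)
  sig <- bandwidth_px / d
  w <- ceiling(4 * sig)
  for (i in seq_len(nrow(centroids))) {
    # grid coordinates of the point (grid cell centers at (k - 0.5) * d + 0.5)
    pr <- (centroids[i, 1] - 0.5) / d + 0.5
    pc <- (centroids[i, 2] - 0.5) / d + 0.5
    r0 <- max(1L, floor(pr - w)); r1 <- min(gr, ceiling(pr + w))
    c0 <- max(1L, floor(pc - w)); c1 <- min(gc, ceiling(pc + w))
    k <- exp(-outer(((r0:r1) - pr)^2, ((c0:c1) - pc)^2, `+`) / (2 * sig^2))
    map[r0:r1, c0:c1] <- map[r0:r1, c0:c1] + k / sum(k)
  }
  list(map = map, bandwidth_px = bandwidth_px, downsample = d,
       total_count = nrow(centroids))
}

#' Count target cells near reference objects
#'
#' A target cell is counted for a reference object if its centroid lies
#' within the morphological dilation of the object by a Euclidean disc
#' of radius `distance_px` — equivalently, if the Euclidean distance
#' from the centroid's pixel to the object's pixel set is at most
#' `distance_px`. Targets in range of several objects count once per
#' object but once in the deduplicated total. This is the
#' "expand objects, then count cells within the distance" analysis used
#' for e.g. macrophages around ductular structures.
#'
#' @param reference integer label mask of reference objects.
#' @param targets cell table (rows already filtered to the condition of
#'   interest) with `centroid_row`/`centroid_col` (1-based).
#' @param distance_px dilation radius (integer >= 0; no default — the
#'   radius is a study design choice).
#' @param tissue_area optional area (px) for the per-area normalization.
#' @return list: `per_object` (data.frame object_id, count),
#'   `total_unique`, and `per_area` when `tissue_area` is given.
#' @export
neighbor_count <- function(reference, targets, distance_px, tissue_area = NULL) {
  distance_px <- as.integer(distance_px)
  if (distance_px < 0L) stop_param("distance must be >= 0")
  n_obj <- max(reference)
  cr <- pmin(pmax(round(targets$centroid_row), 1L), nrow(reference))
  cc <- pmin(pmax(round(targets$centroid_col), 1L), ncol(reference))
  counted <- rep(FALSE, nrow(targets))
  counts <- integer(n_obj)
  if (n_obj > 0L && nrow(targets) > 0L) {
    kern <- disc_kernel(distance_px)
    for (obj in seq_len(n_obj)) {
      m <- (reference == obj) * 1
      dil <- if (distance_px == 0L) m else EBImage::imageData(EBImage::dilate(m, kern))
      hit <- dil[cbind(cr, cc)] > 0
      counts[obj] <- sum(hit)
      counted <- counted | hit
    }
  }
  out <- list(per_object = data.frame(object_id = seq_len(n_obj), count = counts),
              total_unique = sum(counted))
  if (!is.null(tissue_area)) out$per_area <- sum(counted) / tissue_area
  out
}

#' Delineate tumor and extratumoral regions
#'
#' Operationalizes "collagen-encapsulated structures containing
#' proliferating (PCNA-positive) nuclei": the collagen mask is
#' morphologically closed (sealing capsule gaps up to the closing
#' radius); enclosed areas are the holes of the closed mask (background
#' components not touching the image border); an enclosed area of at
#' least `min_region_px` containing at least `min_pcna_nuclei` PCNA+
#' nucleus centroids becomes a tumor region. All remaining tissue forms
#' a single extratumoral region.
#'
#' @param collagen logical collagen mask.
#' @param pcna_nuclei label mask of PCNA-positive nuclei, or an n x 2
#'   matrix of their centroids (1-based).
#' @param closing_px closing disc radius (default 10).
#' @param min_pcna_nuclei minimum PCNA+ nuclei per tumor region
#'   (default 10).
#' @param min_region_px minimum enclosed area.
#' @return list of class `region_mask`: `labels` (integer matrix; tumor
#'   regions 1..K, extratumoral = K+1), `classes` (data.frame region_id,
#'   class), `n_tumor`.
#' @export
define_regions <- function(collagen, pcna_nuclei, closing_px = 10L,
                           min_pcna_nuclei = 10L, min_region_px = 500L) {
  collagen <- collagen != 0
  if (is.matrix(pcna_nuclei) && !is.integer(pcna_nuclei[1]) && ncol(pcna_nuclei) == 2) {
    cent <- pcna_nuclei
  } else {
    lab <- pcna_nuclei
    n <- max(lab)
    cent <- if (n > 0) label_centroids(lab) else matrix(numeric(0), 0, 2)
  }
  closed <- if (closing_px > 0)
    EBImage::imageData(EBImage::closing(collagen * 1, disc_kernel(closing_px))) > 0
  else collagen
  holes <- EBImage::imageData(EBImage::bwlabel((!closed) * 1))
  border_labels <- unique(c(holes[1, ], holes[nrow(holes), ], holes[, 1], holes[, ncol(holes)]))
  hole_ids <- setdiff(seq_len(max(holes)), c(0L, border_labels))

  labels <- matrix(0L, nrow(collagen), ncol(collagen))
  k <- 0L
  if (length(hole_ids)) {
    areas <- tabulate(holes[holes > 0], nbins = max(holes))
    pr <- pmin(pmax(round(cent[, 1]), 1L), nrow(collagen))
    pc <- pmin(pmax(round(cent[, 2]), 1L), ncol(collagen))
    for (h in hole_ids) {
      if (areas[h] < min_region_px) next
      n_in <- if (nrow(cent)) sum(holes[cbind(pr, pc)] == h) else 0L
      if (n_in >= min_pcna_nuclei) {
        k <- k + 1L
        labels[holes == h] <- k
      }
    }
  }
  extral <- k + 1L
  labels[labels == 0L] <- extral
  classes <- data.frame(region_id = seq_len(extral),
                        class = c(rep("tumor", k), "extratumoral"))
  structure(list(labels = labels, classes = classes, n_tumor = k),
            class = "region_mask")
}

label_centroids <- function(lab) {
  n <- max(lab)
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  cbind(tapply(rows, lab[idx], mean), tapply(cols, lab[idx], mean))[seq_len(n), , drop = FALSE]
}

#' Per-region phenotype composition
#'
#' Assigns each cell to the region containing its centroid and reports
#' per-region phenotype counts, fractions of all cells in the region,
#' and fractions of the region's macrophage compartment (the KC + MoMF
#' subset), the convention used when comparing Kupffer versus
#' monocyte-derived macrophage contributions per region.
#'
#' @param regions a `region_mask` from [define_regions()].
#' @param table gated cell table with centroids and `phenotype`.
#' @param macrophage_phenotypes labels forming the macrophage
#'   compartment.
#' @return data.frame: region_id, class, phenotype, n_cells,
#'   fraction_of_region, fraction_of_macrophages.
#' @export
region_composition <- function(regions, table,
                               macrophage_phenotypes = c("KC", "MoMF")) {
  labs <- regions$labels
  pr <- pmin(pmax(round(table$centroid_row), 1L), nrow(labs))
  pc <- pmin(pmax(round(table$centroid_col), 1L), ncol(labs))
  region_of_cell <- labs[cbind(pr, pc)]
  out <- list()
  for (rid in regions$classes$region_id) {
    sel <- region_of_cell == rid
    n_reg <- sum(sel)
    n_mac <- sum(sel & table$phenotype %in% macrophage_phenotypes)
    for (p in unique(table$phenotype)) {
      np <- sum(sel & table$phenotype == p)
      out[[length(out) + 1L]] <- data.frame(
        region_id = rid,
        class = regions$classes$class[regions$classes$region_id == rid],
        phenotype = p, n_cells = np,
        fraction_of_region = if (n_reg > 0) np / n_reg else NaN,
        fraction_of_macrophages = if (p %in% macrophage_phenotypes && n_mac > 0)
          np / n_mac else NA_real_)
    }
  }
  do.call(rbind, out)
}
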