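#' Compute per-pixel features for trainable segmentation
#'
#' The standard trainable-segmentation feature bank: for every scale
#' sigma, the Gaussian-smoothed intensity, the gradient magnitude of the
#' smoothed image (central differences) and the Laplacian-of-Gaussian;
#' plus the raw intensity. Feature count is `3 * length(scales) + 1`.
#'
#' @param img numeric matrix.
#' @param scales positive smoothing scales (pixels).
#' @return 3-D array H x W x F with named feature planes.
#' @export
compute_pixel_features <- function(img, scales = c(1, 2, 4)) {
  img <- as_pixel_matrix(img)
  if (!length(scales) || any(scales <= 0)) stop_param("scales must be positive")
  planes <- list(raw = img)
  for (s in scales) {
    sm <- EBImage::imageData(EBImage::gblur(img, sigma = s))
    gr <- grad_row(sm); gc <- grad_col(sm)
    planes[[paste0("gauss_", s)]] <- sm
    planes[[paste0("gradmag_", s)]] <- sqrt(gr^2 + gc^2)
    planes[[paste0("log_", s)]] <- laplacian(sm)
  }
  out <- array(unlist(planes, use.names = FALSE),
               dim = c(dim(img), length(planes)),
               dimnames = list(NULL, NULL, names(planes)))
  out
}

grad_row <- function(m) {
  nr <- nrow(m)
  (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
}
grad_col <- function(m) {
  nc <- ncol(m)
  (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
}
laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(2:nr, nr), ] + m[c(1, 1:(nr - 1)), ] + m[, c(2:nc, nc)] + m[, c(1, 1:(nc - 1))] - 4 * m
}

#' Automatic brush labels from intensity quantiles
#'
#' Unattended stand-in for interactive brush strokes: pixels in the top
#' quantile become foreground seeds, pixels in the bottom quantile
#' background seeds, everything else stays unlabeled. A deterministic
#' subsample caps the number of labeled pixels per class.
#'
#' @param img numeric matrix.
#' @param fg_quantile,bg_quantile intensity quantiles for seeds.
#' @param max_per_class cap on labeled pixels per class.
#' @param seed subsampling seed.
#' @return integer matrix: 0 unlabeled, 1 background, 2 foreground.
#' @export
auto_brush_labels <- function(img, fg_quantile = 0.995, bg_quantile = 0.5,
                              max_per_class = 2000L, seed = 1L) {
  img <- as_pixel_matrix(img)
  qs <- quantile(img, c(bg_quantile, fg_quantile))
  lab <- matrix(0L, nrow(img), ncol(img))
  with_seed(seed, {
    bg <- which(img <= qs[1]); fg <- which(img >= qs[2])
    if (length(bg) > max_per_class) bg <- sample(bg, max_per_class)
    if (length(fg) > max_per_class) fg <- sample(fg, max_per_class)
    lab[bg] <- 1L; lab[fg] <- 2L
  })
  lab
}

#' Train a pixel classifier from sparse brush labels
#'
#' Fits a probability random forest on the labeled pixels of one or more
#' feature stacks. Deterministic for a fixed seed.
#'
#' @param features a feature stack from [compute_pixel_features()], or a
#'   list of stacks.
#' @param brush_labels integer matrix (or list): 0 = unlabeled, k = class
#'   k; at least two classes with >= 50 pixels each.
#' @param class_names optional names for classes 1..K (default
#'   `"class1"`... with 2 classes: `"background"`, `"foreground"`).
#' @param num_trees forest size.
#' @param seed RNG seed for the forest.
#' @return A `pixel_classifier` object; training accuracy is stored in
#'   `$train_accuracy`.
#' @export
train_pixel_classifier <- function(features, brush_labels, class_names = NULL,
                                   num_trees = 50L, seed = 1L) {
  if (!is.list(features)) { features <- list(features); brush_labels <- list(brush_labels) }
  Xs <- list(); ys <- list()
  for (i in seq_along(features)) {
    f <- features[[i]]; lab <- brush_labels[[i]]
    sel <- which(lab != 0L)
    flat <- matrix(f, nrow = prod(dim(f)[1:2]), ncol = dim(f)[3])
    Xs[[i]] <- flat[sel, , drop = FALSE]
    ys[[i]] <- lab[sel]
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop_input("brush labels must contain at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 50L))
    stop_input("each class needs >= 50 labeled pixels (got ",
               paste(cnt, collapse = ", "), ")")
  if (is.null(class_names))
    class_names <- if (length(classes) == 2L) c("background", "foreground")
      else paste0("class", classes)
  feat_names <- dimnames(features[[1]])[[3]]
  colnames(X) <- feat_names
  d <- data.frame(X, .class = factor(class_names[match(y, classes)], levels = class_names))
  fit <- ranger::ranger(dependent.variable.name = ".class", data = d,
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1)
  pred <- predict(fit, d, num.threads = 1)$predictions
  acc <- mean(class_names[max.col(pred)] == as.character(d$.class))
  structure(list(model = fit, class_names = class_names,
                 feature_names = feat_names, train_accuracy = acc,
                 version = "cycloplex-classifier-1"),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("pixel_classifier (", x$version, "): classes ",
      paste(x$class_names, collapse = ", "),
      "; training accuracy ", signif(x$train_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Save / load a pixel classifier
#' @param clf a `pixel_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(clf, path) { saveRDS(clf, path); invisible(path) }

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "pixel_classifier")) stop_input("not a pixel_classifier file")
  clf
}

#' Predict class probabilities for every pixel
#'
#' @param clf a `pixel_classifier`.
#' @param img numeric matrix; features are recomputed with the scales
#'   encoded in the classifier's feature names.
#' @return 3-D array H x W x classes of probabilities (sum to 1).
#' @export
predict_probabilities <- function(clf, img) {
  scales <- classifier_scales(clf)
  f <- compute_pixel_features(img, scales)
  flat <- matrix(f, nrow = prod(dim(f)[1:2]), ncol = dim(f)[3])
  colnames(flat) <- dimnames(f)[[3]]
  p <- predict(clf$model, data.frame(flat), num.threads = 1)$predictions
  array(p, dim = c(dim(img), ncol(p)),
        dimnames = list(NULL, NULL, colnames(p)))
}

classifier_scales <- function(clf) {
  s <- grep("^gauss_", clf$feature_names, value = TRUE)
  as.numeric(sub("^gauss_", "", s))
}

#' Binary mask from a pixel classifier
#'
#' Thresholds the class probability map at `p_min`, then removes
#' connected components (4-connectivity) smaller than `min_object_px`.
#'
#' @param clf a `pixel_classifier`.
#' @param img numeric matrix.
#' @param class_name which class forms the mask (default
#'   `"foreground"`).
#' @param p_min probability threshold in (0, 1].
#' @param min_object_px minimum component area kept.
#' @return logical matrix.
#' @export
predict_mask <- function(clf, img, class_name = "foreground",
                         p_min = 0.5, min_object_px = 20L) {
  if (!class_name %in% clf$class_names)
    stop_param("unknown class '", class_name, "'; classifier knows: ",
               paste(clf$class_names, collapse = ", "))
  p <- predict_probabilities(clf, img)[, , class_name]
  filter_small_components(p >= p_min, min_object_px)
}

filter_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Identify nuclei in the nuclear-counterstain channel
#'
#' Foreground by a global Otsu threshold (or a supplied probability map
#' thresholded at 0.5, or an explicit threshold), holes filled, then —
#' when `split = TRUE` — touching nuclei are separated by watershed on
#' the Euclidean distance transform (nearby peaks merged through the
#' watershed tolerance). Objects outside the size range are removed and
#' labels renumbered 1..K.
#'
#' @param dapi numeric matrix.
#' @param threshold `"otsu"`, a numeric cutoff, or a probability matrix.
#' @param size_range `c(min_px, max_px)` kept object area.
#' @param split separate touching nuclei.
#' @param watershed_tolerance minimum distance-transform depth between
#'   peaks that remain separate objects.
#' @return integer label matrix (0 = background, labels contiguous 1..K).
#' @export
identify_nuclei <- function(dapi, threshold = "otsu", size_range = c(10L, 2000L),
                            split = TRUE, watershed_tolerance = 1) {
  dapi <- as_pixel_matrix(dapi)
  if (size_range[1] >= size_range[2]) stop_param("size_range min must be < max")
  fg <- if (is.matrix(threshold)) {
    threshold >= 0.5
  } else if (identical(threshold, "otsu")) {
    dapi > otsu_threshold(dapi)
  } else {
    dapi > as.numeric(threshold)
  }
  if (!any(fg)) {
    warning("empty nucleus foreground")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  fg <- EBImage::imageData(EBImage::fillHull(fg * 1)) > 0
  if (split) {
    dm <- EBImage::distmap(fg * 1)
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(fg * 1))
  }
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= size_range[1] & areas <= size_range[2])
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  out
}

# Otsu's threshold on a 256-bin histogram of the raw intensity range.
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((img - rng[1]) / diff(rng) * 256)) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

#' Assemble per-cell records from nuclei and marker masks
#'
#' Expands each nucleus by up to `cell_expand_px` without crossing
#' another cell's territory (nearest-nucleus tie-break, via seeded
#' propagation on the distance transform), then records per marker the
#' mean intensity over the cell footprint and a positivity flag: the
#' fraction of the footprint covered by the marker's binary mask must
#' reach `coverage_min`. Markers listed in `nuclear_markers` (e.g. a
#' nuclear proliferation marker) are scored on the nucleus footprint
#' only.
#'
#' @param nuclei integer label matrix from [identify_nuclei()].
#' @param marker_masks named list of logical matrices.
#' @param marker_images named list of numeric matrices (same frame).
#' @param cell_expand_px expansion distance (default 3).
#' @param coverage_min positive-call coverage fraction in (0, 1].
#' @param nuclear_markers markers evaluated on the nucleus footprint.
#' @return data.frame: `cell_id, centroid_row, centroid_col, area_px`,
#'   `mean_<marker>`, `pos_<marker>` (1-based centroids).
#' @export
assemble_cells <- function(nuclei, marker_masks = list(), marker_images = list(),
                           cell_expand_px = 3L, coverage_min = 0.3,
                           nuclear_markers = character()) {
  shp <- dim(nuclei)
  for (m in c(marker_masks, marker_images)) {
    if (!all(dim(m) == shp)) stop_input("marker frames do not match the nucleus frame")
  }
  n <- max(nuclei)
  markers <- union(names(marker_masks), names(marker_images))
  if (n == 0L) {
    tab <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0))
    for (m in markers) { tab[[paste0("mean_", m)]] <- numeric(0); tab[[paste0("pos_", m)]] <- logical(0) }
    return(tab)
  }

  territory <- expand_labels(nuclei, cell_expand_px)
  idx_all <- which(territory > 0)
  cell_px <- split(idx_all, territory[idx_all])
  nuc_idx <- which(nuclei > 0)
  nuc_px <- split(nuc_idx, nuclei[nuc_idx])

  rows <- (seq_along(nuclei) - 1L) %% shp[1] + 1L
  cols <- (seq_along(nuclei) - 1L) %/% shp[1] + 1L
  tab <- data.frame(
    cell_id = seq_len(n),
    centroid_row = vapply(seq_len(n), function(i) mean(rows[nuc_px[[as.character(i)]]]), numeric(1)),
    centroid_col = vapply(seq_len(n), function(i) mean(cols[nuc_px[[as.character(i)]]]), numeric(1)),
    area_px = vapply(seq_len(n), function(i) length(nuc_px[[as.character(i)]]), integer(1))
  )
  for (m in markers) {
    foot <- if (m %in% nuclear_markers) nuc_px else cell_px
    if (!is.null(marker_images[[m]])) {
      img <- marker_images[[m]]
      tab[[paste0("mean_", m)]] <- vapply(seq_len(n), function(i) {
        px <- foot[[as.character(i)]]
        if (length(px)) mean(img[px]) else 0
      }, numeric(1))
    }
    if (!is.null(marker_masks[[m]])) {
      msk <- marker_masks[[m]]
      cov <- vapply(seq_len(n), function(i) {
        px <- foot[[as.character(i)]]
        if (length(px)) mean(msk[px]) else 0
      }, numeric(1))
      tab[[paste0("pos_", m)]] <- cov >= coverage_min
    }
  }
  tab
}

# Expand labeled objects by up to `px` using nearest-seed propagation on
# the distance transform, constrained to pixels within `px` of a seed.
expand_labels <- function(labels, px) {
  if (px <= 0) return(labels)
  # distmap of the inverted mask: distance from each background pixel to
  # the nearest object pixel
  dist_bg <- EBImage::imageData(EBImage::distmap((labels == 0L) * 1))
  mask <- (labels > 0L) | (dist_bg <= px)
  prop <- EBImage::propagate(x = dist_bg, seeds = labels, mask = mask, lambda = 1e-4)
  matrix(as.integer(EBImage::imageData(prop)), nrow(labels), ncol(labels))
}
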