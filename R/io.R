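#' Read per-cycle channel images
#'
#' Each cycle is one grayscale TIFF (single- or multi-page, one page per
#' channel, in the channel order declared by the panel). Integer TIFFs
#' are widened losslessly to doubles without rescaling, so quantitative
#' comparisons across cycles are preserved; float TIFFs are read as
#' stored.
#'
#' @param paths character vector, one TIFF per cycle, in cycle order.
#' @param panel a [panel_config()].
#' @return A list of cycles; each cycle is a named list of numeric
#'   matrices keyed by marker name.
#' @export
read_cycle_images <- function(paths, panel) {
  if (length(paths) != length(panel$cycles))
    stop_input("got ", length(paths), " image path(s) for ",
               length(panel$cycles), " panel cycle(s)")
  lapply(seq_along(paths), function(i) {
    pages <- read_tiff_pages(paths[[i]])
    markers <- cycle_markers(panel, i)
    if (length(pages) != length(markers))
      stop_input("cycle ", i - 1L, ": ", length(pages), " page(s) in ", paths[[i]],
                 " but panel declares ", length(markers), " channel(s)")
    shapes <- vapply(pages, dim, integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop_input("cycle ", i - 1L, ": channel shapes differ within ", paths[[i]])
    names(pages) <- markers
    pages
  })
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop_input("image not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # tolerate single-channel stored as planar
    storage.mode(p) <- "double"
    p
  })
}

#' Write one or more grayscale channels as a TIFF
#'
#' Intensities are stored as 16-bit integers (rounded, clipped to
#' the 0..65535 range); pass `bits = 32` for float storage of data
#' already scaled to \[0, 1\] (e.g. probability maps).
#'
#' @param channels a numeric matrix or list of matrices (pages).
#' @param path output path.
#' @param bits 16 (integer) or 32 (float in \[0,1\]).
#' @export
write_image_tiff <- function(channels, path, bits = 16) {
  if (is.matrix(channels)) channels <- list(channels)
  if (bits == 16) {
    pages <- lapply(channels, function(m) {
      m <- round(m)
      m[m < 0] <- 0; m[m > 65535] <- 65535
      m / 65535
    })
  } else if (bits == 32) {
    pages <- lapply(channels, function(m) {
      if (any(m < 0) || any(m > 1)) stop_param("32-bit float TIFF requires values in [0, 1]")
      m
    })
  } else stop_param("bits must be 16 or 32")
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write an integer label mask as a 16-bit TIFF
#' @param mask integer matrix, 0 = background.
#' @param path output path.
#' @export
write_label_tiff <- function(mask, path) {
  if (max(mask) > 65535) stop_param("more than 65535 labels cannot be stored as 16-bit")
  write_image_tiff(mask, path, bits = 16)
}

#' Read a label mask written by [write_label_tiff()]
#' @param path TIFF path.
#' @export
read_label_tiff <- function(path) {
  m <- read_tiff_pages(path)[[1]]
  storage.mode(m) <- "integer"
  m
}

# ---- cell tables -----------------------------------------------------------

#' Write a cell table to CSV
#'
#' Stable column order: `cell_id, centroid_row, centroid_col, area_px`,
#' then `mean_<marker>` and `pos_<marker>` in panel order, `phenotype`,
#' `region`. Centroids are written 0-based (pixel-center convention).
#'
#' @param table a data.frame as produced by [assemble_cells()].
#' @param path output CSV path.
#' @export
write_cell_table <- function(table, path) {
  out <- table
  out$centroid_row <- out$centroid_row - 1
  out$centroid_col <- out$centroid_col - 1
  mean_cols <- grep("^mean_", names(out), value = TRUE)
  pos_cols <- grep("^pos_", names(out), value = TRUE)
  extra <- intersect(c("phenotype", "region"), names(out))
  cols <- c("cell_id", "centroid_row", "centroid_col", "area_px", mean_cols, pos_cols, extra)
  out <- out[, cols, drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 7))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table written by [write_cell_table()]
#' @param path CSV path.
#' @return data.frame with 1-based centroids (internal convention).
#' @export
read_cell_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$centroid_row <- d$centroid_row + 1
  d$centroid_col <- d$centroid_col + 1
  for (cl in grep("^pos_", names(d), value = TRUE)) d[[cl]] <- as.logical(d[[cl]])
  d
}

#' Write a QC overlay PNG
#'
#' Renders a grayscale image (auto-scaled) with an optional mask
#' boundary drawn in color, for visual inspection of segmentation or
#' registration results.
#'
#' @param img numeric matrix (background image).
#' @param path output PNG path.
#' @param mask optional binary mask whose boundary is overlaid.
#' @param color overlay color as length-3 RGB in \[0,1\].
#' @export
write_qc_png <- function(img, path, mask = NULL, color = c(1, 0.2, 0.2)) {
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  rgb <- array(g, dim = c(dim(g), 3))
  if (!is.null(mask)) {
    edge <- mask_boundary(mask != 0)
    for (k in 1:3) { p <- rgb[, , k]; p[edge] <- color[k]; rgb[, , k] <- p }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

mask_boundary <- function(m) {
  er <- EBImage::erode(m * 1, EBImage::makeBrush(3, "box"))
  m & !(er > 0)
}
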