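#' Subtract smooth background by morphological opening
#'
#' The background estimate is the grayscale morphological opening of the
#' image with a disc of the given radius (a rolling-ball-equivalent
#' operator: it passes broad background but removes features narrower
#' than the disc). The result is `clip(img - opening, 0)`, so output
#' never exceeds input and a constant image maps to zero.
#'
#' @param img numeric matrix.
#' @param radius_px disc radius in pixels (default 50).
#' @return matrix of same shape.
#' @export
subtract_background <- function(img, radius_px = 50) {
  img <- as_pixel_matrix(img)
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop_param("radius_px must be >= 1")
  if (radius_px >= min(dim(img)) / 2)
    stop_param("radius_px (", radius_px, ") must be below half the smallest image dimension")
  brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  # grayscale morphology clamps to [0,1]; opening is positively
  # scale-equivariant, so normalize by the max and scale back
  s <- max(img)
  if (s <= 0) return(img * 0)
  bg <- s * EBImage::imageData(EBImage::opening(img / s, brush))
  pmax(img - bg, 0)
}

#' Estimate the autofluorescence mixing scale
#'
#' Fits the slope of `img` against a designated autofluorescence (AF)
#' channel over high-AF pixels, using the least-absolute-deviation line
#' through the origin (the |AF|-weighted median of pixelwise ratios).
#' The LAD fit is robust to genuine marker signal sitting on top of the
#' AF component.
#'
#' @param img marker channel (matrix).
#' @param af AF channel, same shape.
#' @param bg_quantile pixels with AF above this quantile of the AF image
#'   are used (default 0.75).
#' @return nonnegative scale estimate.
#' @export
estimate_af_scale <- function(img, af, bg_quantile = 0.75) {
  img <- as_pixel_matrix(img); af <- as_pixel_matrix(af, "af")
  if (!all(dim(img) == dim(af))) stop_input("img and af must share a shape")
  if (all(af == 0)) stop_input("af channel is identically zero")
  if (bg_quantile <= 0 || bg_quantile >= 1) stop_param("bg_quantile must be in (0, 1)")
  thr <- quantile(af, bg_quantile)
  sel <- af > thr & af > 0
  if (sum(sel) < 100L)
    stop_input("fewer than 100 pixels qualify for AF scale estimation")
  x <- af[sel]; y <- img[sel]
  # weighted median of y/x with weights x minimizes sum |y - s x|
  ratio <- y / x
  o <- order(ratio)
  w <- x[o]
  cum <- cumsum(w) / sum(w)
  s <- ratio[o][which(cum >= 0.5)[1]]
  max(s, 0)
}

#' Subtract a scaled autofluorescence component
#'
#' `clip(img - scale * af, 0)`; never increases any pixel.
#'
#' @param img marker channel.
#' @param af AF channel, same shape.
#' @param scale nonnegative mixing coefficient, e.g. from
#'   [estimate_af_scale()].
#' @export
subtract_autofluorescence <- function(img, af, scale) {
  img <- as_pixel_matrix(img); af <- as_pixel_matrix(af, "af")
  if (!all(dim(img) == dim(af))) stop_input("img and af must share a shape")
  if (scale < 0) stop_param("scale must be >= 0")
  pmax(img - scale * af, 0)
}

#' Extract the collagen mask from a trichrome RGB image
#'
#' Selects pixels by color threshold in HSV space: hue inside the blue
#' window, saturation at least `sat_min` (excludes gray/white), value at
#' most `val_max` (excludes bright white background). Input in \[0,1\] or
#' \[0,255\] is auto-normalized.
#'
#' @param rgb H x W x 3 array.
#' @param hue_window `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @param sat_min minimum saturation.
#' @param val_max maximum value.
#' @return logical matrix.
#' @export
extract_collagen <- function(rgb, hue_window = c(0.50, 0.72),
                             sat_min = 0.25, val_max = 0.98) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop_input("rgb must be an H x W x 3 array")
  if (hue_window[1] >= hue_window[2]) stop_param("degenerate hue window (lo >= hi)")
  if (max(rgb) > 1) rgb <- rgb / 255
  n <- prod(dim(rgb)[1:2])
  hsv <- rgb2hsv(r = as.vector(rgb[, , 1]), g = as.vector(rgb[, , 2]),
                 b = as.vector(rgb[, , 3]), maxColorValue = 1)
  sel <- hsv[1, ] >= hue_window[1] & hsv[1, ] <= hue_window[2] &
    hsv[2, ] >= sat_min & hsv[3, ] <= val_max
  matrix(sel, dim(rgb)[1], dim(rgb)[2])
}

#' Preprocess all channels of every cycle
#'
#' Applies [subtract_background()] to each channel and, when an AF
#' reference is supplied, estimates and subtracts the AF component from
#' each non-nuclear marker channel.
#'
#' @param cycles list of per-cycle channel sets.
#' @param panel a [panel_config()].
#' @param bg_radius_px background-subtraction disc radius.
#' @param af optional AF reference image (already background-subtracted
#'   or raw; it is background-subtracted internally).
#' @return list with `cycles` (processed) and `af_scales` (named vector).
#' @export
preprocess_cycles <- function(cycles, panel, bg_radius_px = 50, af = NULL) {
  af_scales <- c()
  if (!is.null(af)) af <- subtract_background(af, bg_radius_px)
  out <- lapply(seq_along(cycles), function(i) {
    chans <- cycles[[i]]
    lapply(setNames(names(chans), names(chans)), function(m) {
      img <- subtract_background(chans[[m]], bg_radius_px)
      if (!is.null(af) && m != panel$nuclear_channel) {
        s <- estimate_af_scale(img, af)
        af_scales[[m]] <<- s
        img <- subtract_autofluorescence(img, af, s)
      }
      img
    })
  })
  list(cycles = out, af_scales = af_scales)
}
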