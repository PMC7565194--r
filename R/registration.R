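#' Warp an image into the reference frame
#'
#' Resamples a moving-frame image through an affine transform `t`
#' (moving -> reference): output pixel `x` takes the bilinearly
#' interpolated value of the moving image at `t^{-1}(x)`. Pixels whose
#' pre-image falls outside the moving frame are filled with 0 and marked
#' invalid in the returned mask.
#'
#' @param img numeric matrix (moving frame).
#' @param t an [affine_transform()] mapping moving -> reference.
#' @param shape output shape (default: same as input).
#' @param interpolation `"bilinear"` for intensities, `"nearest"` for
#'   label/mask images.
#' @return list with `image` and logical `valid` mask.
#' @export
warp_image <- function(img, t, shape = dim(img),
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  img <- as_pixel_matrix(img)
  ti <- affine_invert(t)
  nr <- shape[1]; nc <- shape[2]
  grid_r <- rep(seq_len(nr), times = nc)
  grid_c <- rep(seq_len(nc), each = nr)
  pre <- affine_apply(ti, cbind(grid_r, grid_c))
  valid <- pre[, 1] >= 1 & pre[, 1] <= nrow(img) & pre[, 2] >= 1 & pre[, 2] <= ncol(img)
  if (interpolation == "nearest") {
    pr <- pmin(pmax(round(pre[, 1]), 1), nrow(img))
    pc <- pmin(pmax(round(pre[, 2]), 1), ncol(img))
    vals <- img[cbind(pr, pc)]
  } else {
    vals <- bilinear_sample(img, pre[, 1], pre[, 2])
  }
  vals[!valid] <- 0
  list(image = matrix(vals, nr, nc), valid = matrix(valid, nr, nc))
}

#' Warp all channels of a cycle
#'
#' Applies one transform to every channel of a cycle with bilinear
#' interpolation and returns the single shared validity mask.
#'
#' @param channels named list of matrices (one cycle).
#' @param t an [affine_transform()].
#' @return list with `channels` and `valid`.
#' @export
warp_cycle <- function(channels, t) {
  out <- lapply(channels, function(ch) warp_image(ch, t))
  list(channels = lapply(out, `[[`, "image"), valid = out[[1]]$valid)
}

#' Estimate the affine transform aligning a moving nuclear image to a reference
#'
#' Two-stage estimate anchored on the nuclear counterstain: (1) a global
#' translation from the cross-correlation peak of the (smoothed,
#' mean-subtracted) images, computed at a coarse pyramid level; (2)
#' derivative-free refinement of the full affine (rotation/scale/shear +
#' translation, parameterized about the image center) maximizing the
#' normalized correlation between the reference and the warped moving
#' image, coarse-to-fine over a multi-resolution pyramid.
#'
#' @param reference,moving numeric matrices of identical shape, both
#'   non-constant (typically DAPI channels).
#' @param levels integer downsampling factors, coarse to fine.
#' @param smooth_sigma Gaussian pre-smoothing sigma (pixels, full
#'   resolution).
#' @param maxit Nelder-Mead iteration budget per level (recycled).
#' @param score_floor similarity below this after refinement triggers a
#'   low-confidence warning (the transform is still returned).
#' @return an [affine_transform()] (moving -> reference) with the final
#'   normalized-correlation score attached.
#' @export
estimate_affine <- function(reference, moving, levels = c(8L, 4L, 2L, 1L),
                            smooth_sigma = 2, maxit = c(300L, 300L, 200L, 60L),
                            score_floor = 0.2) {
  reference <- as_pixel_matrix(reference); moving <- as_pixel_matrix(moving)
  if (!all(dim(reference) == dim(moving))) stop_input("images must share a shape")
  if (sd(reference) == 0 || sd(moving) == 0)
    stop_input("constant image cannot be registered")
  maxit <- rep_len(maxit, length(levels))

  ref_s <- EBImage::imageData(EBImage::gblur(reference, sigma = smooth_sigma))
  mov_s <- EBImage::imageData(EBImage::gblur(moving, sigma = smooth_sigma))
  pyr_ref <- lapply(levels, function(f) downsample_mean(ref_s, f))
  pyr_mov <- lapply(levels, function(f) downsample_mean(mov_s, f))

  # stage 1: global translation at the coarsest level
  f0 <- levels[1]
  shift0 <- xcorr_translation(pyr_ref[[1]], pyr_mov[[1]]) * f0
  center <- (1 + dim(reference)) / 2

  # stage 2: coarse-to-fine refinement about the center
  par <- c(shift0, 0, 0, 0, 0) # t_r, t_c, dm11, dm12, dm21, dm22
  for (k in seq_along(levels)) {
    f <- levels[k]
    ref_k <- pyr_ref[[k]]; mov_k <- pyr_mov[[k]]
    c_k <- (center - 1) / f + 1
    obj <- function(p) {
      tk <- params_to_affine(c(p[1:2] / f, p[3:6]), c_k)
      -ncc_warped(ref_k, mov_k, tk)
    }
    fit <- optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit[k],
                                parscale = c(f, f, 0.01, 0.01, 0.01, 0.01),
                                reltol = 1e-8))
    par <- fit$par
  }
  score <- -fit$value
  if (score < score_floor)
    warning("low registration confidence: similarity ", signif(score, 3))
  out <- params_to_affine(par, center)
  out$score <- score
  out
}

params_to_affine <- function(p, center) {
  M <- matrix(c(1 + p[3], p[5], p[4], 1 + p[6]), 2, 2)
  t <- as.numeric(center) - M %*% as.numeric(center) + p[1:2]
  affine_transform(cbind(M, t))
}

# Integer translation from the circular cross-correlation peak.
xcorr_translation <- function(ref, mov) {
  a <- ref - mean(ref); b <- mov - mean(mov)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  idx <- which.max(cc)
  nr <- nrow(cc)
  d <- c((idx - 1) %% nr, (idx - 1) %/% nr)
  sz <- dim(ref)
  ifelse(d > sz / 2, d - sz, d)
}

# Normalized correlation between ref and mov warped by t, over the valid
# region, on a subsampled pixel grid for speed at fine levels.
ncc_warped <- function(ref, mov, t, max_samples = 150000L) {
  nr <- nrow(ref); nc <- ncol(ref)
  stride <- max(1L, floor(sqrt(nr * nc / max_samples)))
  rows <- seq(1L, nr, by = stride); cols <- seq(1L, nc, by = stride)
  grid_r <- rep(rows, times = length(cols))
  grid_c <- rep(cols, each = length(rows))
  pre <- affine_apply(affine_invert(t), cbind(grid_r, grid_c))
  valid <- pre[, 1] >= 1 & pre[, 1] <= nr & pre[, 2] >= 1 & pre[, 2] <= nc
  if (sum(valid) < 50L) return(-1)
  vals <- bilinear_sample(mov, pre[valid, 1], pre[valid, 2])
  safe_cor(ref[cbind(grid_r[valid], grid_c[valid])], vals)
}

#' Register and warp all cycles into the frame of the first cycle
#'
#' The first cycle is the reference (identity transform). Every later
#' cycle is registered on its nuclear channel with [estimate_affine()]
#' and all its channels are warped into the reference frame.
#'
#' @param cycles list of per-cycle named channel lists.
#' @param panel a [panel_config()] naming the nuclear channel.
#' @param ... passed to [estimate_affine()].
#' @return list with `cycles` (aligned), `transforms`, `validity`
#'   (per-cycle logical masks) and `scores`.
#' @export
align_experiment <- function(cycles, panel, ...) {
  if (!length(cycles)) stop_input("need at least one cycle")
  for (i in seq_along(cycles)) {
    if (!panel$nuclear_channel %in% names(cycles[[i]]))
      stop_config("cycle ", i - 1L, " is missing the nuclear channel '",
                  panel$nuclear_channel, "'")
  }
  ref <- cycles[[1]][[panel$nuclear_channel]]
  transforms <- vector("list", length(cycles))
  validity <- vector("list", length(cycles))
  aligned <- vector("list", length(cycles))
  transforms[[1]] <- affine_identity()
  transforms[[1]]$score <- 1
  aligned[[1]] <- cycles[[1]]
  validity[[1]] <- matrix(TRUE, nrow(ref), ncol(ref))
  if (length(cycles) > 1) {
    for (i in 2:length(cycles)) {
      t_i <- estimate_affine(ref, cycles[[i]][[panel$nuclear_channel]], ...)
      w <- warp_cycle(cycles[[i]], t_i)
      transforms[[i]] <- t_i
      aligned[[i]] <- w$channels
      validity[[i]] <- w$valid
    }
  }
  list(cycles = aligned, transforms = transforms, validity = validity,
       scores = vapply(transforms, `[[`, numeric(1), "score"))
}

#' Largest rectangle inside the intersection of validity masks
#'
#' Finds the largest axis-aligned rectangle fully contained in the
#' pixelwise AND of all masks (largest-rectangle-under-histogram scan
#' over the row/column validity profile). Used to crop non-merging
#' borders after alignment.
#'
#' @param validity_masks list of logical matrices, same shape.
#' @return named integer vector `c(row0, col0, row1, col1)`, 0-based
#'   half-open (so `row1 - row0` is the height).
#' @export
crop_common_region <- function(validity_masks) {
  if (!length(validity_masks)) stop_input("need at least one mask")
  inter <- Reduce(`&`, validity_masks)
  if (!any(inter)) stop_input("validity masks have empty intersection")
  nr <- nrow(inter); nc <- ncol(inter)
  heights <- integer(nc)
  best <- c(area = 0L, row0 = 0L, col0 = 0L, row1 = 0L, col1 = 0L)
  for (r in seq_len(nr)) {
    heights <- ifelse(inter[r, ], heights + 1L, 0L)
    # largest rectangle in histogram `heights`, stack-based
    stack_pos <- integer(0); stack_h <- integer(0)
    for (cx in seq_len(nc + 1L)) {
      h <- if (cx <= nc) heights[cx] else 0L
      start <- cx
      while (length(stack_h) && stack_h[length(stack_h)] > h) {
        ph <- stack_h[length(stack_h)]; pp <- stack_pos[length(stack_pos)]
        stack_h <- stack_h[-length(stack_h)]; stack_pos <- stack_pos[-length(stack_pos)]
        area <- ph * (cx - pp)
        if (area > best["area"])
          best <- c(area = area, row0 = r - ph, col0 = pp - 1L, row1 = r, col1 = cx - 1L)
        start <- pp
      }
      if (h > 0L && (!length(stack_h) || stack_h[length(stack_h)] < h)) {
        stack_pos <- c(stack_pos, start); stack_h <- c(stack_h, h)
      }
    }
  }
  out <- as.integer(best[c("row0", "col0", "row1", "col1")])
  names(out) <- c("row0", "col0", "row1", "col1")
  out
}

#' Crop an image to a rectangle from [crop_common_region()]
#' @param img matrix.
#' @param rect 0-based half-open rectangle.
#' @export
crop_apply <- function(img, rect) {
  img[(rect[["row0"]] + 1L):rect[["row1"]], (rect[["col0"]] + 1L):rect[["col1"]], drop = FALSE]
}

#' Least-squares affine from landmark pairs
#'
#' Estimates the affine mapping brightfield (e.g. trichrome) coordinates
#' into the fluorescence reference frame from at least three
#' non-collinear point correspondences.
#'
#' @param src n x 2 matrix of (row, col) points in the brightfield frame.
#' @param dst n x 2 matrix of matching points in the reference frame.
#' @return an [affine_transform()]; the RMS residual is attached as
#'   attribute `rms_residual`.
#' @export
align_brightfield <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3L || nrow(dst) != nrow(src))
    stop_param("need at least 3 matched point pairs")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L) stop_param("landmark points are collinear")
  beta <- qr.solve(X, dst) # 3 x 2: columns are (row', col') coefficients
  M <- t(beta[1:2, ]); tvec <- beta[3, ]
  mat <- unname(cbind(M, tvec))
  dimnames(mat) <- NULL
  t_out <- affine_transform(mat)
  resid <- dst - X %*% beta
  attr(t_out, "rms_residual") <- sqrt(mean(resid^2))
  t_out
}
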