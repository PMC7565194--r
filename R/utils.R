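# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(errorCondition(paste0(...), class = c("cycloplex_config_error", "error")))
stop_input <- function(...) stop(errorCondition(paste0(...), class = c("cycloplex_input_error", "error")))
stop_param <- function(...) stop(errorCondition(paste0(...), class = c("cycloplex_param_error", "error")))

#' Evaluate an expression with a private RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals do
#' not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Exact Euclidean disc as a 0/1 kernel matrix of size (2r+1)^2.
# Offsets (dr, dc) are included iff dr^2 + dc^2 <= r^2 (integer arithmetic),
# so dilation with this kernel matches a pairwise squared-distance test.
disc_kernel <- function(radius) {
  r <- as.integer(radius)
  if (r < 0L) stop_param("disc radius must be >= 0")
  d <- outer((-r):r, (-r):r, function(a, b) a * a + b * b)
  (d <= r * r) * 1L
}

# Block-mean downsampling by an integer factor (crops to a multiple).
downsample_mean <- function(img, f) {
  f <- as.integer(f)
  if (f == 1L) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  x <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  x <- array(x, dim = c(f, nr %/% f, f, nc %/% f))
  colMeans(colMeans(aperm(x, c(1, 3, 2, 4))))
}

# Bilinear sampling of img at (possibly fractional) 1-based coordinates.
# Out-of-range coordinates are clamped; callers track validity separately.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r0 <- pmin(pmax(r0, 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(c0, 1), nc); c1 <- pmin(c0 + 1, nc)
  i00 <- img[cbind(r0, c0)]; i01 <- img[cbind(r0, c1)]
  i10 <- img[cbind(r1, c0)]; i11 <- img[cbind(r1, c1)]
  (1 - fr) * (1 - fc) * i00 + (1 - fr) * fc * i01 +
    fr * (1 - fc) * i10 + fr * fc * i11
}

# Pearson correlation that tolerates constant inputs (returns 0).
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  stats::cor(a, b)
}

as_pixel_matrix <- function(img, what = "image") {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (!is.matrix(img) || !is.numeric(img))
    stop_input(what, " must be a numeric matrix")
  img
}
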