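#' Planar affine transforms
#'
#' A transform maps moving-frame coordinates to reference-frame
#' coordinates: `(row', col') = M %*% (row, col) + t`. It is stored as a
#' 2x3 matrix `[M | t]` acting on 1-based (row, col) pixel coordinates;
#' serialization converts to the 0-based convention used in files.
#'
#' @param matrix 2x3 numeric matrix.
#' @param score optional similarity score attached by registration.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, score = NA_real_) {
  if (!is.matrix(matrix) || any(dim(matrix) != c(2, 3)))
    stop_param("affine matrix must be 2x3")
  dt <- det(matrix[, 1:2])
  if (abs(dt) < 1e-12) stop_param("affine linear part is singular")
  if (abs(dt) < 0.5 || abs(dt) > 2)
    warning("affine determinant ", signif(dt, 4),
            " outside the plausible [0.5, 2] range for re-mounted sections")
  structure(list(matrix = matrix, score = score), class = "affine_transform")
}

#' Identity transform
#' @export
affine_identity <- function() affine_transform(cbind(diag(2), c(0, 0)))

#' Apply a transform to points
#'
#' @param t an `affine_transform`.
#' @param pts n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
affine_apply <- function(t, pts) {
  pts <- rbind(t(as.matrix(pts))) # 2 x n
  out <- t$matrix[, 1:2] %*% pts + t$matrix[, 3]
  t(out)
}

#' Invert a transform
#' @param t an `affine_transform`.
#' @export
affine_invert <- function(t) {
  Mi <- solve(t$matrix[, 1:2])
  affine_transform(cbind(Mi, -Mi %*% t$matrix[, 3]), score = t$score)
}

#' Compose transforms: apply `b` first, then `a`
#' @param a,b `affine_transform` objects.
#' @export
affine_compose <- function(a, b) {
  M <- a$matrix[, 1:2] %*% b$matrix[, 1:2]
  t <- a$matrix[, 1:2] %*% b$matrix[, 3] + a$matrix[, 3]
  affine_transform(cbind(M, t))
}

#' Build a transform from rotation/scale/translation about a center
#'
#' @param rotation_deg rotation in degrees (counter-clockwise in (row, col)).
#' @param scale isotropic scale factor.
#' @param translation length-2 (row, col) shift in pixels.
#' @param center length-2 (row, col) fixed point of rotation/scaling.
#' @export
affine_from_params <- function(rotation_deg = 0, scale = 1,
                               translation = c(0, 0), center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  M <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- as.numeric(center) - M %*% as.numeric(center) + as.numeric(translation)
  affine_transform(cbind(M, t))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform (moving -> reference, 1-based row/col)\n")
  print(signif(x$matrix, 6))
  if (!is.na(x$score)) cat("similarity score:", signif(x$score, 4), "\n")
  invisible(x)
}

# 1-based internal matrix <-> 0-based serialized matrix.
# x0 = x1 - 1, so t0 = M %*% 1 + t1 - 1.
affine_to_zero_based <- function(t) {
  M <- t$matrix[, 1:2]
  cbind(M, M %*% c(1, 1) + t$matrix[, 3] - 1)
}
affine_from_zero_based <- function(m03, score = NA_real_) {
  M <- m03[, 1:2]
  affine_transform(cbind(M, m03[, 3] - M %*% c(1, 1) + 1), score = score)
}

#' Write per-cycle transforms to CSV
#'
#' One row per cycle with the six coefficients (0-based coordinate
#' convention) and the similarity score.
#' @param transforms list of `affine_transform`.
#' @param path output CSV path.
#' @export
write_transforms <- function(transforms, path) {
  rows <- lapply(seq_along(transforms), function(i) {
    m <- affine_to_zero_based(transforms[[i]])
    data.frame(cycle = i - 1L,
               a_rr = m[1, 1], a_rc = m[1, 2], t_r = m[1, 3],
               a_cr = m[2, 1], a_cc = m[2, 2], t_c = m[2, 3],
               score = transforms[[i]]$score)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read per-cycle transforms written by [write_transforms()]
#' @param path CSV path.
#' @return list of `affine_transform` in cycle order.
#' @export
read_transforms <- function(path) {
  d <- read.csv(path)
  lapply(seq_len(nrow(d)), function(i) {
    m <- matrix(c(d$a_rr[i], d$a_cr[i], d$a_rc[i], d$a_cc[i], d$t_r[i], d$t_c[i]), 2, 3)
    affine_from_zero_based(m, score = d$score[i])
  })
}
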