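#' Construct a 2D affine transform
#'
#' Represents the mapping between the light-microscopy (LM) and electron-
#' microscopy (EM) pixel frames as `p' = A %*% p + b`. Coordinates are
#' 0-based pixel centers, `(x, y) = (column, row)`, throughout the package.
#'
#' @param A 2x2 linear part (must be invertible).
#' @param b Length-2 translation.
#' @param direction Either `"em_to_lm"` or `"lm_to_em"`; a tag recording
#'   which frame is the source.
#' @return An `affine2d` object.
#' @export
affine2d <- function(A, b = c(0, 0), direction = c("em_to_lm", "lm_to_em")) {
  direction <- match.arg(direction)
  A <- matrix(as.numeric(A), 2L, 2L)
  b <- as.numeric(b)
  stopifnot(length(b) == 2L)
  if (abs(det(A)) <= 1e-12) {
    stop("affine linear part is singular (|det| <= 1e-12)")
  }
  structure(list(A = A, b = b, direction = direction), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d (", x$direction, ")\n", sep = "")
  m <- cbind(x$A, x$b)
  dimnames(m) <- list(c("x'", "y'"), c("x", "y", "1"))
  print(m)
  invisible(x)
}

#' Build an affine transform from scale, rotation and translation
#'
#' Convenience constructor for similarity transforms,
#' `p' = s * R(theta) %*% p + t`.
#'
#' @param scale Isotropic scale factor.
#' @param rotation_deg Rotation angle, degrees, counterclockwise in the
#'   `(x, y)` plane.
#' @param translation Length-2 translation (pixels of the target frame).
#' @inheritParams affine2d
#' @export
affine_similarity <- function(scale = 1, rotation_deg = 0,
                              translation = c(0, 0),
                              direction = c("em_to_lm", "lm_to_em")) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  affine2d(scale * R, translation, direction = match.arg(direction))
}

#' Apply an affine transform to points
#'
#' @param tf An [affine2d()].
#' @param pts Numeric matrix or data frame with columns x, y (n x 2).
#' @return n x 2 matrix of transformed points.
#' @export
affine_apply <- function(tf, pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stop("pts must be an n x 2 matrix")
  out <- pts %*% t(tf$A)
  out[, 1L] <- out[, 1L] + tf$b[1L]
  out[, 2L] <- out[, 2L] + tf$b[2L]
  colnames(out) <- c("x", "y")
  out
}

#' Invert an affine transform
#'
#' @param tf An [affine2d()].
#' @return The inverse `affine2d`, with the direction tag swapped.
#' @export
affine_invert <- function(tf) {
  Ai <- solve(tf$A)
  dir <- if (tf$direction == "em_to_lm") "lm_to_em" else "em_to_lm"
  affine2d(Ai, -as.vector(Ai %*% tf$b), direction = dir)
}

#' Fit a least-squares affine transform to control-point pairs
#'
#' Estimates the 2D affine map minimizing the summed squared distance
#' between transformed source points and their target counterparts. In the
#' CLEM workflow the source points are picked on the EM overview and the
#' targets on the LM image (5-10 landmark pairs are typically sufficient).
#'
#' @param points_src n x 2 matrix of source-frame points (x, y).
#' @param points_dst n x 2 matrix of corresponding target-frame points.
#' @param direction Direction tag for the fitted transform, default
#'   `"em_to_lm"`.
#' @param warn_rms_px Warn (do not fail) when the root-mean-square residual
#'   exceeds this many target-frame pixels. Default 5.
#' @return A list with `transform` ([affine2d()]), `residuals` (per-point
#'   Euclidean residual, target pixels) and `rms`.
#' @examples
#' src <- cbind(c(0, 10, 0, 7), c(0, 0, 10, 3))
#' fit <- fit_affine(src, src)   # identity, residuals 0
#' @export
fit_affine <- function(points_src, points_dst,
                       direction = c("em_to_lm", "lm_to_em"),
                       warn_rms_px = 5) {
  direction <- match.arg(direction)
  src <- as.matrix(points_src)
  dst <- as.matrix(points_dst)
  if (ncol(src) != 2L || ncol(dst) != 2L) stop("points must be n x 2")
  n <- nrow(src)
  if (n != nrow(dst)) stop("point sets differ in length")
  if (n < 3L) stop("at least 3 control-point pairs are required, got ", n)
  # collinear sources leave the 6 affine coefficients underdetermined
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L) stop("control points are collinear")
  beta <- qr.solve(X, dst)              # 3 x 2: [A^T; b^T]
  tf <- affine2d(t(beta[1:2, ]), beta[3L, ], direction = direction)
  res <- sqrt(rowSums((affine_apply(tf, src) - dst)^2))
  rms <- sqrt(mean(res^2))
  if (rms > warn_rms_px) {
    warning(sprintf("affine fit rms residual %.3g px exceeds %g px",
                    rms, warn_rms_px))
  }
  list(transform = tf, residuals = res, rms = rms)
}

#' Read / write control points
#'
#' Control points are stored as CSV with columns `em_x, em_y, lm_x, lm_y`
#' (0-based pixel coordinates).
#'
#' @param path CSV file path.
#' @return `read_control_points`: data frame with those four columns.
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path)
  need <- c("em_x", "em_y", "lm_x", "lm_y")
  if (!all(need %in% names(df))) {
    stop("control point CSV must have columns ", paste(need, collapse = ", "))
  }
  df[need]
}

#' @rdname read_control_points
#' @param points Data frame with columns `em_x, em_y, lm_x, lm_y`.
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Store / load a transform as a 6-number text sidecar
#'
#' @param tf An [affine2d()].
#' @param path Output text file.
#' @export
write_affine <- function(tf, path) {
  lines <- c(paste("direction", tf$direction),
             paste(format(c(tf$A[1, 1], tf$A[1, 2], tf$b[1],
                            tf$A[2, 1], tf$A[2, 2], tf$b[2]),
                          digits = 17), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  lines <- readLines(path)
  direction <- sub("^direction\\s+", "", lines[1L])
  v <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  affine2d(matrix(c(v[1], v[4], v[2], v[5]), 2L, 2L), c(v[3], v[6]),
           direction = direction)
}
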