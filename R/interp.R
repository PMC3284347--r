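# Vectorized image resampling primitives shared by registration, mosaics
# and tomography.  Coordinates are 1-based (row, col) fractional positions
# in the source image.

# Catmull-Rom cubic convolution at arbitrary positions, edge replication.
# rows/cols: equal-length numeric vectors of sample positions.
interp_bicubic <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  tr <- rows - r0; tc <- cols - c0
  wr <- .catmull_weights(tr); wc <- .catmull_weights(tc)
  out <- numeric(length(rows))
  for (i in 1:4) {
    ri <- pmin(pmax(r0 + (i - 2L), 1), h)
    acc <- numeric(length(rows))
    for (j in 1:4) {
      cj <- pmin(pmax(c0 + (j - 2L), 1), w)
      acc <- acc + wc[[j]] * img[ri + (cj - 1) * h]
    }
    out <- out + wr[[i]] * acc
  }
  out
}

.catmull_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list(-0.5 * t3 + t2 - 0.5 * t,
       1.5 * t3 - 2.5 * t2 + 1,
       -1.5 * t3 + 2 * t2 + 0.5 * t,
       0.5 * t3 - 0.5 * t2)
}

# Bilinear sampling with value 0 outside the image (tomography convention).
interp_bilinear_zero <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  tr <- rows - r0; tc <- cols - c0
  out <- numeric(length(rows))
  for (dr in 0:1) for (dc in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc
    wgt <- (if (dr == 0) 1 - tr else tr) * (if (dc == 0) 1 - tc else tc)
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w & wgt > 0
    if (any(ok))
      out[ok] <- out[ok] + wgt[ok] * img[rr[ok] + (cc[ok] - 1) * h]
  }
  out
}

#' Translate an image by a fractional pixel shift
#'
#' Resamples so that `out[r, c] = img[r + dy, c + dx]` (bicubic, edge
#' replication) -- i.e. `(dy, dx)` is added to the image's own coordinates,
#' matching the shift convention of [phase_correlate()]: translating the
#' moving image by its measured shift lands it on the reference.
#'
#' @param img Numeric matrix.
#' @param dy,dx Row/column shift in pixels (may be fractional).
#' @return Translated matrix, same shape.
#' @export
translate_image <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  rows <- rep(seq_len(h), times = w) + dy
  cols <- rep(seq_len(w), each = h) + dx
  matrix(interp_bicubic(img, rows, cols), h, w)
}

# Rotate about the image center by `deg` (counter-clockwise in standard x/y,
# i.e. in (row, col) the sampling grid is rotated clockwise), bilinear,
# zeros outside.  Used by the forward projector.
rotate_image <- function(img, deg) {
  h <- nrow(img); w <- ncol(img)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  th <- deg * pi / 180
  r <- rep(seq_len(h), times = w) - cr
  c <- rep(seq_len(w), each = h) - cc
  rows <- cr + cos(th) * r - sin(th) * c
  cols <- cc + sin(th) * r + cos(th) * c
  matrix(interp_bilinear_zero(img, rows, cols), h, w)
}
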