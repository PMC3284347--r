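#' @title Phase-correlation image registration
#' @description FFT-based translation measurement via the whitened
#'   cross-power spectrum: a pure translation between two images appears as
#'   an impulse in the inverse transform, robust to global intensity changes
#'   such as the contrast change across an absorption edge.  Used by every
#'   pipeline stage (energy stacks, 2E pairs, mosaic tiles, tomographic
#'   jitter).
#' @name phasecorr
NULL

.hann2 <- function(h, w) {
  wh <- if (h > 1) 0.5 - 0.5 * cos(2 * pi * (0:(h - 1)) / (h - 1)) else 1
  ww <- if (w > 1) 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1)) else 1
  outer(wh, ww)
}

.wrap_signed <- function(idx0, n) ifelse(idx0 >= n / 2, idx0 - n, idx0)

# 3-point parabolic vertex offset, clamped to [-0.5, 0.5]
.parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
}

#' Measure the translation between two images by phase correlation
#'
#' Computes the whitened cross-power spectrum
#' `R = F_ref * Conj(F_mov) / |F_ref * Conj(F_mov)|` (with an epsilon floor
#' on the magnitude), inverse-transforms it and locates the correlation
#' peak.  The peak index is mapped to a signed shift in
#' `[-H/2, H/2) x [-W/2, W/2)`; sub-pixel refinement uses a separable
#' 3-point parabolic fit.  A raised-cosine (Hann) window is applied by
#' default because real stacks are not periodic; disable it only for
#' genuinely circular data.
#'
#' The returned shift `(dy, dx)` is the displacement to *add* to the moving
#' image's coordinates to land on the reference, i.e.
#' `translate_image(moving, dy, dx)` aligns `moving` onto `reference`.
#'
#' @param reference,moving Numeric matrices of identical shape; at least one
#'   must be non-constant.
#' @param window Apply a Hann window before the FFT (default `TRUE`).
#' @param subpixel Refine the peak to sub-pixel precision (default `TRUE`).
#' @return A `shift` object: list with `dy`, `dx` and `peak_quality` (the
#'   normalized correlation peak height in `[0, 1]`).
#' @export
phase_correlate <- function(reference, moving, window = TRUE, subpixel = TRUE) {
  if (!identical(dim(reference), dim(moving)))
    stop("reference and moving images must have identical shape")
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  if (all(a == 0) && all(b == 0))
    stop("no spectral content: both images are constant")
  if (window) {
    wnd <- .hann2(nrow(a), ncol(a))
    a <- a * wnd; b <- b * wnd
  }
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cs <- Fa * Conj(Fb)
  mag <- Mod(cs)
  eps <- 1e-12 * max(mag)
  if (max(mag) == 0) stop("no spectral content: zero cross spectrum")
  r <- Re(stats::fft(cs / pmax(mag, eps), inverse = TRUE)) / length(cs)
  h <- nrow(r); w <- ncol(r)
  pk <- arrayInd(which.max(r), dim(r))
  pr <- pk[1]; pc <- pk[2]
  off_r <- off_c <- 0
  if (subpixel) {
    rm1 <- (pr - 2) %% h + 1; rp1 <- pr %% h + 1
    cm1 <- (pc - 2) %% w + 1; cp1 <- pc %% w + 1
    off_r <- .parabolic_offset(r[rm1, pc], r[pr, pc], r[rp1, pc])
    off_c <- .parabolic_offset(r[pr, cm1], r[pr, pc], r[pr, cp1])
  }
  sp_r <- .wrap_signed(pr - 1 + off_r, h)
  sp_c <- .wrap_signed(pc - 1 + off_c, w)
  structure(list(dy = -sp_r, dx = -sp_c,
                 peak_quality = max(0, min(1, r[pr, pc]))),
            class = "shift")
}

#' @export
print.shift <- function(x, ...) {
  cat(sprintf("<shift> dy = %+.3f px, dx = %+.3f px (peak quality %.3f)\n",
              x$dy, x$dx, x$peak_quality))
  invisible(x)
}

#' Align every frame of a stack onto a reference frame
#'
#' Measures each frame's shift against the chosen reference frame by
#' [phase_correlate()] and translates it (bicubic resampling, edge
#' replication).  Frames whose correlation peak falls below `q_min` are
#' flagged -- not dropped -- and a warning lists them; whether to discard
#' them is the caller's decision.
#'
#' @param stack An `energy_stack` or `projection_series`.
#' @param reference_index Index of the frame everything is aligned to.
#' @param q_min Minimum acceptable peak quality (default 0.05).
#' @return List with the aligned `stack` and a data frame `shifts`
#'   (`dy`, `dx`, `peak_quality`, `flagged`).
#' @export
align_stack <- function(stack, reference_index = 1, q_min = 0.05) {
  n <- n_frames(stack)
  if (reference_index < 1 || reference_index > n)
    stop("reference_index out of range")
  ref <- get_frame(stack, reference_index)
  shifts <- data.frame(dy = numeric(n), dx = numeric(n),
                       peak_quality = numeric(n), flagged = logical(n))
  out <- stack$data
  for (i in seq_len(n)) {
    if (i == reference_index) {
      shifts[i, ] <- list(0, 0, 1, FALSE)
      next
    }
    s <- phase_correlate(ref, get_frame(stack, i))
    shifts[i, ] <- list(s$dy, s$dx, s$peak_quality, s$peak_quality < q_min)
    out[i, , ] <- translate_image(get_frame(stack, i), s$dy, s$dx)
  }
  if (any(shifts$flagged))
    warning("low correlation quality for frame(s) ",
            paste(which(shifts$flagged), collapse = ", "),
            " (peak_quality < ", q_min, "); frames kept but flagged")
  stack$data <- out
  list(stack = stack, shifts = shifts)
}

#' Rotation and scale registration via log-polar phase correlation
#'
#' Optional second registration stage (off by default in all pipelines):
#' the magnitudes of the centered Fourier spectra are resampled onto a
#' log-polar grid, where rotation and isotropic scaling become translations
#' that [phase_correlate()] can measure.  Translation-only phase correlation
#' remains the primary mechanism; use this only when frames are visibly
#' rotated or the magnification metadata is untrusted.
#'
#' @param reference,moving Numeric matrices of identical, square-ish shape.
#' @param n_theta,n_r Log-polar grid resolution.
#' @return List with `rotation_deg` (rotation of `moving` relative to
#'   `reference`), `scale`, and `peak_quality`.
#' @export
phase_correlate_rotscale <- function(reference, moving,
                                     n_theta = 180L, n_r = 128L) {
  lp <- function(img) {
    wnd <- .hann2(nrow(img), ncol(img))
    sp <- Mod(stats::fft((img - mean(img)) * wnd))
    h <- nrow(sp); w <- ncol(sp)
    sp <- sp[c((h %/% 2 + 1):h, 1:(h %/% 2)), c((w %/% 2 + 1):w, 1:(w %/% 2))]
    cr <- h %/% 2 + 1; cc <- w %/% 2 + 1
    r_max <- min(h, w) / 2 - 1
    lr <- exp(seq(log(2), log(r_max), length.out = n_r))
    th <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
    rows <- cr + outer(sin(th), lr)
    cols <- cc + outer(cos(th), lr)
    matrix(interp_bicubic(sp, as.vector(rows), as.vector(cols)), n_theta, n_r)
  }
  A <- lp(reference); B <- lp(moving)
  s <- phase_correlate(A, B, window = TRUE)
  r_max <- min(dim(reference)) / 2 - 1
  dlog <- (log(r_max) - log(2)) / (n_r - 1)
  list(rotation_deg = -s$dy * 180 / n_theta,
       scale = exp(-s$dx * dlog),
       peak_quality = s$peak_quality)
}
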