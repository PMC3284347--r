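#' @title Parallel-beam tomographic reconstruction
#' @description Sinogram handling, projection jitter correction, filtered
#'   back projection (FBP) and iterative algebraic reconstruction (ART,
#'   Kaczmarz row action), region-of-interest reconstruction, rotation-axis
#'   finding and a forward projector used as the testing oracle.  TXM
#'   projections are treated as parallel-beam: the objective forms an image,
#'   so rays through the sample are effectively parallel at these fields of
#'   view.
#' @name tomo
NULL

#' Construct a sinogram for one slice row
#'
#' @param data Numeric matrix `(n_angles, n_detector_cols)`.
#' @param angles_deg Strictly increasing stage angles in degrees.
#' @param center Rotation-axis column (1-based, may be fractional); defaults
#'   to the geometric center `(W + 1) / 2`.
#' @return A `sinogram` object.
#' @export
sinogram <- function(data, angles_deg, center = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(angles_deg))
    stop("nrow(data) must equal length(angles_deg)")
  if (is.null(center)) center <- (ncol(data) + 1) / 2
  if (center < 1 || center > ncol(data)) stop("center outside the detector")
  structure(list(data = data, angles_deg = as.numeric(angles_deg),
                 center = center),
            class = "sinogram")
}

#' Forward (Radon) projection of a square image
#'
#' Line integrals computed by rotating the image about its center (bilinear
#' sampling, zeros outside) and summing columns; detector center is the
#' geometric image center.  This is the oracle the reconstruction tests are
#' checked against and the measurement model of the tomography phantoms.
#'
#' @param image Square numeric matrix.
#' @param angles_deg Projection angles in degrees.
#' @return A [sinogram()] of dimension `(n_angles, ncol(image))`.
#' @export
forward_project <- function(image, angles_deg) {
  if (nrow(image) != ncol(image)) stop("image must be square")
  p <- t(vapply(angles_deg,
                function(a) colSums(rotate_image(image, a)),
                numeric(ncol(image))))
  sinogram(p, angles_deg)
}

.ramp_filter <- function(npad, window = c("ramlak", "shepp", "hann")) {
  window <- match.arg(window)
  f <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / npad  # cycles/sample
  H <- abs(f)
  fc <- 0.5
  if (window == "shepp") {
    s <- ifelse(f == 0, 1, sin(pi * f / (2 * fc)) / (pi * f / (2 * fc)))
    H <- H * s
  } else if (window == "hann") {
    H <- H * 0.5 * (1 + cos(pi * f / fc))
  }
  H
}

# Filter each sinogram row with the apodized ramp (zero-padded FFT).
.filter_sinogram <- function(p, window) {
  w <- ncol(p)
  npad <- 2^ceiling(log2(max(2 * w, 64)))
  H <- .ramp_filter(npad, window)
  out <- matrix(0, nrow(p), w)
  for (i in seq_len(nrow(p))) {
    row <- c(p[i, ], rep(0, npad - w))
    out[i, ] <- Re(stats::fft(stats::fft(row) * H, inverse = TRUE))[1:w] / npad
  }
  out
}

.angular_weight <- function(angles_deg) {
  # integration weight per projection, radians; each line orientation
  # counted once (360-degree scans sample every line twice)
  n <- length(angles_deg)
  if (n < 2) return(pi)
  step <- stats::median(diff(angles_deg))
  span <- diff(range(angles_deg)) + step
  w <- step * pi / 180
  if (span > 270) w <- w / 2
  w
}

#' Filtered back projection of one sinogram
#'
#' Rows are ramp-filtered in the frequency domain (zero-padded to the next
#' power of two at least twice the detector width, apodization selectable)
#' and back-projected with linear interpolation.  A `roi` box restricts
#' back projection to a sub-grid, reconstructing a local region at full
#' resolution without reconstructing the whole slice.
#'
#' @param sino A [sinogram()].
#' @param filter `"ramlak"`, `"shepp"` or `"hann"`.
#' @param roi Optional `c(r0, c0, h, w)` (1-based) sub-grid of the full
#'   `W x W` reconstruction grid.
#' @return Numeric matrix: the reconstructed slice (full grid or ROI).
#' @export
fbp_reconstruct <- function(sino, filter = c("ramlak", "shepp", "hann"),
                            roi = NULL) {
  filter <- match.arg(filter)
  angles <- sino$angles_deg
  if (length(angles) >= 2) {
    step <- stats::median(diff(angles))
    if (diff(range(angles)) + step < 120)
      warning("angular span < 120 degrees: limited-angle artifacts expected")
  }
  q <- .filter_sinogram(sino$data, filter)
  w <- ncol(sino$data)
  cr <- (w + 1) / 2
  if (is.null(roi)) roi <- c(1, 1, w, w)
  rows <- roi[1]:(roi[1] + roi[3] - 1)
  cols <- roi[2]:(roi[2] + roi[4] - 1)
  dr <- rep(rows, times = length(cols)) - cr
  dc <- rep(cols, each = length(rows)) - cr
  acc <- numeric(length(dr))
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    t <- sino$center + (-sin(th)) * dr + cos(th) * dc
    t0 <- floor(t); ft <- t - t0
    v <- numeric(length(t))
    ok0 <- t0 >= 1 & t0 <= w
    ok1 <- t0 + 1 >= 1 & t0 + 1 <= w
    qa <- q[a, ]
    v[ok0] <- v[ok0] + (1 - ft[ok0]) * qa[t0[ok0]]
    v[ok1] <- v[ok1] + ft[ok1] * qa[t0[ok1] + 1]
    acc <- acc + v
  }
  matrix(acc * .angular_weight(angles), length(rows), length(cols))
}

# Per-ray bilinear footprints consistent with forward_project(): for each
# angle, the rotated sampling grid is decomposed into (pixel index, weight)
# pairs grouped by detector column.  Returns a list of rays in angle-major
# order: list(p = value, idx = pixel indices, w = weights, n2 = |a|^2).
.build_rays <- function(sino, n) {
  angles <- sino$angles_deg
  w <- ncol(sino$data)
  cr <- (n + 1) / 2; cc <- (n + 1) / 2
  det_c <- sino$center
  rays <- vector("list", length(angles) * w)
  pos <- 0L
  grid_r <- rep(seq_len(n), times = w)            # sample index along ray
  grid_c <- rep(seq_len(w), each = n)             # detector column
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    sr <- cr + cos(th) * (grid_r - cr) - sin(th) * (grid_c - det_c)
    sc <- cc + sin(th) * (grid_r - cr) + cos(th) * (grid_c - det_c)
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    idx_all <- integer(0); w_all <- numeric(0); ray_all <- integer(0)
    for (dr in 0:1) for (dc in 0:1) {
      rr <- r0 + dr; cci <- c0 + dc
      wt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- rr >= 1 & rr <= n & cci >= 1 & cci <= n & wt > 1e-12
      idx_all <- c(idx_all, rr[ok] + (cci[ok] - 1L) * n)
      w_all <- c(w_all, wt[ok])
      ray_all <- c(ray_all, grid_c[ok])
    }
    ord <- order(ray_all, idx_all)
    idx_all <- idx_all[ord]; w_all <- w_all[ord]; ray_all <- ray_all[ord]
    # collapse duplicate pixel entries within each ray
    key_change <- c(TRUE, diff(ray_all) != 0 | diff(idx_all) != 0)
    grp <- cumsum(key_change)
    idx_u <- idx_all[key_change]
    ray_u <- ray_all[key_change]
    w_u <- as.numeric(rowsum(w_all, grp))
    split_at <- c(which(c(TRUE, diff(ray_u) != 0)), length(ray_u) + 1L)
    for (k in seq_len(length(split_at) - 1L)) {
      sel <- split_at[k]:(split_at[k + 1L] - 1L)
      pos <- pos + 1L
      rays[[pos]] <- list(p = sino$data[a, ray_u[split_at[k]]],
                          idx = idx_u[sel], w = w_u[sel],
                          n2 = sum(w_u[sel]^2))
    }
  }
  rays[seq_len(pos)]
}

#' Iterative algebraic reconstruction (Kaczmarz ART)
#'
#' Row-action Kaczmarz updates cycling through rays in angle-major order:
#' `x <- x + relax * (p_i - <a_i, x>) / |a_i|^2 * a_i`, with bilinear ray
#' footprints matching [forward_project()].  Optionally clamps `x >= 0`
#' after each full sweep.  If the data residual grows for three consecutive
#' sweeps the iteration stops early with a warning.
#'
#' ART needs many fewer views than FBP for comparable quality, which is its
#' point for dose- or time-limited tomography.
#'
#' @param sino A [sinogram()].
#' @param n_iter Number of full sweeps (>= 1).
#' @param relax Relaxation factor in `(0, 1]` (default 0.25).
#' @param nonneg Clamp negative values after each sweep (default `TRUE`).
#' @param x0 Optional starting slice (defaults to zeros).
#' @return Reconstructed `W x W` slice with attribute `"residuals"` (the
#'   relative data residual per sweep).
#' @export
art_reconstruct <- function(sino, n_iter = 10, relax = 0.25, nonneg = TRUE,
                            x0 = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (relax <= 0 || relax > 1) stop("relax must be in (0, 1]")
  n <- ncol(sino$data)
  rays <- .build_rays(sino, n)
  x <- if (is.null(x0)) numeric(n * n) else as.numeric(x0)
  p_norm <- sqrt(sum(sino$data^2))
  residuals <- numeric(n_iter)
  n_grow <- 0
  for (sweep in seq_len(n_iter)) {
    for (ray in rays) {
      if (ray$n2 == 0) next
      res <- ray$p - sum(ray$w * x[ray$idx])
      x[ray$idx] <- x[ray$idx] + (relax * res / ray$n2) * ray$w
    }
    if (nonneg) x[x < 0] <- 0
    rss <- 0
    for (ray in rays) {
      d <- ray$p - sum(ray$w * x[ray$idx])
      rss <- rss + d * d
    }
    residuals[sweep] <- if (p_norm > 0) sqrt(rss) / p_norm else sqrt(rss)
    if (sweep > 1 && residuals[sweep] > residuals[sweep - 1]) {
      n_grow <- n_grow + 1
      if (n_grow >= 3) {
        warning("ART residual grew for 3 consecutive sweeps; stopping at sweep ",
                sweep)
        residuals <- residuals[seq_len(sweep)]
        break
      }
    } else n_grow <- 0
  }
  out <- matrix(x, n, n)
  attr(out, "residuals") <- residuals
  out
}

#' Correct per-angle projection jitter
#'
#' Random stage/motor jitter displaces each projection and must be removed
#' before reconstruction.  `method = "auto"` chains phase correlation
#' between consecutive angles, accumulates the relative shifts, removes the
#' smooth component attributable to genuine parallax, and by default adds a
#' center-of-mass consistency refinement: in parallel-beam geometry the
#' projected centroid must follow `a + b sin(theta) + c cos(theta)`
#' horizontally and stay constant vertically, so the residual of each
#' frame's intensity centroid about that model is residual jitter.
#' `method = "template"` tracks a user-chosen feature box by normalized
#' cross-correlation instead, then detrends identically.
#'
#' The parallax model (`detrend`) is `"harmonic"` (`1, sin, cos` of angle;
#' exact for rigid parallel-beam motion) or `"poly"` (polynomial of order
#' `detrend_order`).  Jitter that happens to lie in the parallax model's
#' span is unidentifiable by any consistency-based method and is absorbed
#' into the trend.
#'
#' @param series A `projection_series`.
#' @param method `"auto"` or `"template"`.
#' @param detrend `"harmonic"` (default) or `"poly"`.
#' @param detrend_order Polynomial order when `detrend = "poly"`.
#' @param refine_com Apply the center-of-mass refinement (default `TRUE`;
#'   requires the specimen to stay fully inside the field of view).
#' @param box For `"template"`: `c(r0, c0, h, w)` feature box in frame 1.
#' @param max_shift For `"template"`: search radius in px (default 16).
#' @return List with the corrected `series` and a data frame `shifts`
#'   (`angle_deg`, `dy`, `dx`).
#' @export
jitter_correct <- function(series, method = c("auto", "template"),
                           detrend = c("harmonic", "poly"),
                           detrend_order = 2, refine_com = TRUE,
                           box = NULL, max_shift = 16) {
  method <- match.arg(method)
  detrend <- match.arg(detrend)
  n <- n_frames(series)
  shifts <- data.frame(angle_deg = series$angles_deg,
                       dy = numeric(n), dx = numeric(n))
  if (n < 2) return(list(series = series, shifts = shifts))
  ang <- series$angles_deg
  if (method == "auto") {
    rel <- matrix(0, n, 2)
    for (i in 2:n) {
      s <- phase_correlate(get_frame(series, i - 1), get_frame(series, i))
      rel[i, ] <- c(s$dy, s$dx)
    }
    cum <- apply(rel, 2, cumsum)
  } else {
    if (is.null(box)) stop("template method needs a feature box c(r0,c0,h,w)")
    cum <- .track_template(series, box, max_shift)
  }
  cum <- .detrend_shifts(cum, ang, detrend, detrend_order)
  out <- series$data
  for (i in seq_len(n))
    if (max(abs(cum[i, ])) > 1e-9)
      out[i, , ] <- translate_image(get_frame(series, i), cum[i, 1], cum[i, 2])
  if (method == "auto" && refine_com) {
    # fixed-point iteration: large initial errors shift mass into the edge
    # replication zone, so one linear correction is not exact
    for (iter in 1:4) {
      cent <- t(vapply(seq_len(n), function(i) {
        f <- out[i, , ]         # keep noise zero-mean: no clipping
        m <- sum(f)
        if (m <= 0) return(c(NA_real_, NA_real_))
        c(sum(row(f) * f), sum(col(f) * f)) / m
      }, numeric(2)))
      if (anyNA(cent)) break
      resid <- .detrend_shifts(cent, ang, "harmonic", detrend_order)
      cum <- cum + resid
      for (i in seq_len(n))
        out[i, , ] <- translate_image(get_frame(series, i),
                                      cum[i, 1], cum[i, 2])
      if (max(abs(resid)) < 0.05) break
    }
  }
  series$data <- out
  shifts$dy <- cum[, 1]; shifts$dx <- cum[, 2]
  list(series = series, shifts = shifts)
}

.detrend_shifts <- function(cum, angles_deg, detrend, detrend_order) {
  n <- nrow(cum)
  X <- if (detrend == "harmonic") {
    th <- angles_deg * pi / 180
    cbind(1, sin(th), cos(th))
  } else {
    outer(angles_deg - mean(angles_deg), 0:min(detrend_order, n - 1), "^")
  }
  apply(cum, 2, function(v) stats::lm.fit(X, v)$residuals)
}

# Normalized cross-correlation tracking of one feature box across frames.
# Returns the per-frame correction shift (feature displacement vs frame 1).
.track_template <- function(series, box, max_shift) {
  n <- n_frames(series)
  r0 <- box[1]; c0 <- box[2]; bh <- box[3]; bw <- box[4]
  tpl <- get_frame(series, 1)[r0:(r0 + bh - 1), c0:(c0 + bw - 1)]
  tpl <- tpl - mean(tpl)
  tn <- sqrt(sum(tpl^2))
  cum <- matrix(0, n, 2)
  H <- dim(series$data)[2]; W <- dim(series$data)[3]
  for (i in 2:n) {
    frame <- get_frame(series, i)
    best <- c(-Inf, 0, 0)
    for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
      rr <- r0 + dy; cc <- c0 + dx
      if (rr < 1 || cc < 1 || rr + bh - 1 > H || cc + bw - 1 > W) next
      win <- frame[rr:(rr + bh - 1), cc:(cc + bw - 1)]
      win <- win - mean(win)
      den <- tn * sqrt(sum(win^2))
      ncc <- if (den > 0) sum(tpl * win) / den else 0
      if (ncc > best[1]) best <- c(ncc, dy, dx)
    }
    cum[i, ] <- best[2:3]
  }
  cum
}

#' Reconstruct a volume slice by slice
#'
#' Extracts the per-row sinogram of each requested slice from a
#' jitter-corrected projection series and reconstructs it independently
#' with a shared rotation center.
#'
#' @param series A `projection_series` (angle, H, W), jitter-corrected.
#' @param algorithm `"fbp"` or `"art"`.
#' @param slices Integer vector of slice rows (default: all rows).
#' @param center Shared rotation-axis column; `NULL` for geometric center,
#'   `"auto"` to estimate from the middle slice with
#'   [find_rotation_center()].
#' @param roi Optional ROI box passed to [fbp_reconstruct()] (FBP only).
#' @param ... Further arguments to the slice reconstructor.
#' @return 3D array `(n_slices, h, w)` of reconstructed slices.
#' @export
reconstruct_volume <- function(series, algorithm = c("fbp", "art"),
                               slices = NULL, center = NULL, roi = NULL, ...) {
  algorithm <- match.arg(algorithm)
  bad <- which(apply(series$data, 1, function(f) any(!is.finite(f))))
  if (length(bad))
    stop("non-finite pixels in projection at angle ",
         series$angles_deg[bad[1]], " deg")
  H <- dim(series$data)[2]
  if (is.null(slices)) slices <- seq_len(H)
  mid <- sinogram(series$data[, slices[(length(slices) + 1) %/% 2], ],
                  series$angles_deg)
  ctr <- if (is.null(center)) mid$center
         else if (identical(center, "auto")) find_rotation_center(mid)
         else center
  first <- NULL
  out <- NULL
  for (k in seq_along(slices)) {
    sino <- sinogram(series$data[, slices[k], ], series$angles_deg, center = ctr)
    slice <- if (algorithm == "fbp") fbp_reconstruct(sino, roi = roi, ...)
             else art_reconstruct(sino, ...)
    if (is.null(out)) out <- array(0, dim = c(length(slices), dim(slice)))
    out[k, , ] <- slice
  }
  out
}

#' Estimate the rotation-axis column of a sinogram
#'
#' For a scan spanning ~180 degrees the first and last projections view the
#' sample from opposite sides, so the last row should mirror the first
#' about the rotation axis; the center minimizing the mirror mismatch is
#' searched on a 0.25 px grid.  For ~360-degree scans the 0/180-degree pair
#' is used.  Any other span triggers a warning and returns the geometric
#' center.
#'
#' @param sino A [sinogram()].
#' @param search_frac Search half-range as a fraction of the width.
#' @return Estimated center column (1-based, fractional).
#' @export
find_rotation_center <- function(sino, search_frac = 0.125) {
  ang <- sino$angles_deg
  w <- ncol(sino$data)
  geo <- (w + 1) / 2
  step <- if (length(ang) > 1) stats::median(diff(ang)) else 0
  span <- diff(range(ang)) + step
  if (abs(span - 180) <= 15) {
    p0 <- sino$data[1, ]; p1 <- sino$data[nrow(sino$data), ]
  } else if (abs(span - 360) <= 15) {
    i180 <- which.min(abs(ang - (ang[1] + 180)))
    p0 <- sino$data[1, ]; p1 <- sino$data[i180, ]
  } else {
    warning("angular span ", signif(span, 4),
            " deg is not ~180 or ~360; returning geometric center")
    return(geo)
  }
  cand <- seq(geo - search_frac * w, geo + search_frac * w, by = 0.25)
  cols <- seq_len(w)
  score <- vapply(cand, function(ctr) {
    m <- 2 * ctr - cols                       # mirror position in p1
    ok <- m >= 1 & m <= w
    if (sum(ok) < w / 4) return(Inf)
    pm <- stats::approx(cols, p1, xout = m[ok])$y
    mean((p0[ok] - pm)^2)
  }, numeric(1))
  cand[which.min(score)]
}
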