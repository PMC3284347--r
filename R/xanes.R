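#' @title Per-pixel XANES spectro-imaging
#' @description An aligned, reference-corrected optical-density energy stack
#'   contains one X-ray absorption near-edge spectrum per pixel (up to ~1e6
#'   spectra per field of view).  This module automates their analysis:
#'   edge-jump mapping and noise filtering, regression-based normalization
#'   with slope filtering, half-height edge-energy mapping, edge-energy
#'   histogram clustering, non-negative linear-combination fitting against
#'   reference spectra with per-pixel R-factor maps, correlation-plot
#'   clustering, and RGB phase-map rendering.
#' @name xanes
NULL

#' Configure the edge windows and filter parameters
#'
#' @param pre_lo,pre_hi Pre-edge window bounds, eV.
#' @param post_lo,post_hi Post-edge window bounds, eV.
#' @param E0 Nominal edge energy, eV (`pre_hi < E0 < post_lo`).
#' @param k Noise-filter multiplier: a pixel is kept when its edge jump is
#'   at least `k` times its pre-edge standard deviation.
#' @param slope_min,slope_max Allowed magnitude range of the pre/post-edge
#'   regression slopes, OD per eV.  Pixels whose fitted baseline slope falls
#'   outside are considered un-normalizable and filtered.
#' @param half_level Normalized level defining the edge energy (0.5).
#' @return An `edge_config` object.
#' @export
edge_config <- function(pre_lo, pre_hi, post_lo, post_hi, E0, k = 3,
                        slope_min = 0, slope_max = c(pre = 0.01, post = 0.02),
                        half_level = 0.5) {
  if (!(pre_lo < pre_hi && pre_hi < E0 && E0 < post_lo && post_lo < post_hi))
    stop("window bounds must satisfy pre_lo < pre_hi < E0 < post_lo < post_hi")
  if (k <= 0) stop("k must be > 0")
  if (length(slope_max) == 1) slope_max <- c(pre = slope_max, post = slope_max)
  structure(list(pre_lo = pre_lo, pre_hi = pre_hi, post_lo = post_lo,
                 post_hi = post_hi, E0 = E0, k = k,
                 slope_min = slope_min, slope_max = slope_max,
                 half_level = half_level),
            class = "edge_config")
}

.window_idx <- function(energies, lo, hi, what) {
  idx <- which(energies >= lo & energies <= hi)
  if (length(idx) < 2)
    stop(what, " window [", lo, ", ", hi, "] eV contains ", length(idx),
         " energy point(s); at least 2 are required")
  idx
}

# (n_energies, H, W) -> (n_energies, n_pixels) matrix view
.as_spectra <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, d[1], d[2] * d[3])
}

#' Edge-jump map
#'
#' The edge jump of a pixel is the difference between its mean optical
#' density over the post-edge window and over the pre-edge window.  Because
#' OD is additive in absorber thickness, the edge jump is proportional to
#' the areal concentration of the edge element, so this map doubles as an
#' elemental concentration map.
#'
#' @param stack An aligned, reference-corrected `energy_stack` in OD.
#' @param cfg An [edge_config()].
#' @return `H x W` numeric matrix (OD units).
#' @export
edge_jump_map <- function(stack, cfg) {
  E <- stack$energies_eV
  pre <- .window_idx(E, cfg$pre_lo, cfg$pre_hi, "pre-edge")
  post <- .window_idx(E, cfg$post_lo, cfg$post_hi, "post-edge")
  Y <- .as_spectra(stack)
  d <- dim(stack$data)
  matrix(colMeans(Y[post, , drop = FALSE]) - colMeans(Y[pre, , drop = FALSE]),
         d[2], d[3])
}

#' Noise filter from the edge jump
#'
#' Keeps a pixel when its edge jump is at least `k` times its pre-edge
#' sample standard deviation (the pixel's own XANES noise level); pixels
#' with weaker absorption carry too little signal to analyse.
#'
#' @inheritParams edge_jump_map
#' @param jump Optional precomputed [edge_jump_map()].
#' @return Logical `H x W` mask, `TRUE` = kept.
#' @export
noise_filter <- function(stack, cfg, jump = NULL) {
  if (is.null(jump)) jump <- edge_jump_map(stack, cfg)
  E <- stack$energies_eV
  pre <- .window_idx(E, cfg$pre_lo, cfg$pre_hi, "pre-edge")
  Y <- .as_spectra(stack)[pre, , drop = FALSE]
  sd_pre <- sqrt(colSums(sweep(Y, 2, colMeans(Y))^2) / (nrow(Y) - 1))
  d <- dim(stack$data)
  jump >= cfg$k * matrix(sd_pre, d[2], d[3])
}

# OLS slope/intercept of each pixel's spectrum over an energy window.
.window_regression <- function(Y, E) {
  Ec <- E - mean(E)
  slope <- as.numeric(crossprod(Ec, Y)) / sum(Ec^2)
  intercept <- colMeans(Y) - slope * mean(E)
  list(slope = slope, intercept = intercept)
}

#' Normalize each pixel's XANES to 0 (pre-edge) and 1 (post-edge)
#'
#' Fits a regression line through each pixel's pre-edge window and another
#' through its post-edge window, then rescales the spectrum as
#' `mu_n(E) = (mu(E) - L_pre(E)) / (L_post(E) - L_pre(E))`.  Because all
#' pixels share one energy scan, differing baselines are caused by the
#' sample itself; the regression removes them.  Pixels that cannot be
#' normalized -- baseline slope magnitude outside
#' `[slope_min, slope_max]`, or a non-positive edge step
#' `L_post(E0) - L_pre(E0)` -- are masked and zeroed at all energies, as
#' are pixels already rejected by `mask`.
#'
#' @inheritParams edge_jump_map
#' @param mask Logical mask of pixels to process (e.g. from
#'   [noise_filter()]); rejected pixels are zeroed.
#' @return List: `normalized` (`energy_stack` of normalized spectra, zeroed
#'   where masked), `norm_mask` (pixels that passed the normalization
#'   filter, regardless of `mask`), `combined_mask` (`mask & norm_mask`).
#' @export
normalize_stack <- function(stack, cfg, mask = NULL) {
  E <- stack$energies_eV
  d <- dim(stack$data)
  pre <- .window_idx(E, cfg$pre_lo, cfg$pre_hi, "pre-edge")
  post <- .window_idx(E, cfg$post_lo, cfg$post_hi, "post-edge")
  Y <- .as_spectra(stack)
  fp <- .window_regression(Y[pre, , drop = FALSE], E[pre])
  fq <- .window_regression(Y[post, , drop = FALSE], E[post])
  step0 <- (fq$intercept + fq$slope * cfg$E0) -
           (fp$intercept + fp$slope * cfg$E0)
  ok <- abs(fp$slope) >= cfg$slope_min & abs(fp$slope) <= cfg$slope_max[["pre"]] &
        abs(fq$slope) >= cfg$slope_min & abs(fq$slope) <= cfg$slope_max[["post"]] &
        step0 > 0
  keep <- if (is.null(mask)) ok else ok & as.vector(mask)
  L_pre <- outer(E, fp$slope) + rep(fp$intercept, each = length(E))
  L_post <- outer(E, fq$slope) + rep(fq$intercept, each = length(E))
  den <- L_post - L_pre
  den[abs(den) < 1e-12] <- 1e-12
  Yn <- (Y - L_pre) / den
  Yn[, !keep] <- 0                    # filtered pixels: zero at all energies
  out <- stack
  out$data <- array(Yn, dim = d)
  list(normalized = out,
       norm_mask = matrix(ok, d[2], d[3]),
       combined_mask = matrix(keep, d[2], d[3]))
}

#' Edge-energy map by half-height interpolation
#'
#' Scans each normalized spectrum upward in energy strictly between the
#' pre- and post-edge windows and linearly interpolates the energy of the
#' *first* upward crossing of the half level (0.5) -- more robust against
#' noise than a derivative-based edge position, and robust to post-edge
#' oscillations by taking the first crossing.  Pixels with no crossing get
#' `NaN`.
#'
#' @param normalized Normalized `energy_stack` (from [normalize_stack()]).
#' @param cfg An [edge_config()].
#' @param mask Logical mask; masked-out pixels are `NaN`.
#' @return `H x W` matrix of edge energies (eV), `NaN` where undefined.
#' @export
edge_energy_map <- function(normalized, cfg, mask = NULL) {
  E <- normalized$energies_eV
  d <- dim(normalized$data)
  sel <- which(E > cfg$pre_hi & E < cfg$post_lo)
  if (length(sel) < 2) stop("fewer than 2 energy points between the windows")
  Y <- .as_spectra(normalized)[sel, , drop = FALSE]
  Es <- E[sel]
  lev <- cfg$half_level
  below <- Y[-nrow(Y), , drop = FALSE] < lev
  above <- Y[-1, , drop = FALSE] >= lev
  crossing <- below & above
  first <- apply(crossing, 2, function(z) if (any(z)) which(z)[1] else NA_integer_)
  out <- rep(NaN, ncol(Y))
  has <- !is.na(first)
  i <- first[has]
  cols <- which(has)
  y0 <- Y[cbind(i, cols)]; y1 <- Y[cbind(i + 1L, cols)]
  out[has] <- Es[i] + (lev - y0) / (y1 - y0) * (Es[i + 1L] - Es[i])
  if (!is.null(mask)) out[!as.vector(mask)] <- NaN
  matrix(out, d[2], d[3])
}

#' Histogram of edge energies
#'
#' Bins the edge-energy map on bins aligned to the scan's energy grid (bin
#' width = the scan's energy step, the experimental precision), excluding
#' `NaN` pixels, and records which pixels fall in each bin so bins can be
#' turned into clusters.
#'
#' @param edge_energy Map from [edge_energy_map()].
#' @param energies_eV The scan energy grid (defines bin width/anchoring).
#' @return List: `breaks`, `mids`, `counts`, and `pixels` (list of pixel
#'   index vectors per bin).
#' @export
edge_energy_histogram <- function(edge_energy, energies_eV) {
  step <- stats::median(diff(energies_eV))
  vals <- as.vector(edge_energy)
  valid <- which(is.finite(vals))
  if (!length(valid))
    return(list(breaks = numeric(0), mids = numeric(0),
                counts = integer(0), pixels = list()))
  # bins centered on the scan grid
  first_edge <- energies_eV[1] - step / 2
  bin <- floor((vals[valid] - first_edge) / step)
  rng <- range(bin)
  bins <- rng[1]:rng[2]
  counts <- tabulate(bin - rng[1] + 1L, nbins = length(bins))
  pixels <- split(valid, factor(bin, levels = bins))
  list(breaks = first_edge + c(bins, rng[2] + 1L) * step,
       mids = energies_eV[1] + bins * step,
       counts = counts,
       pixels = unname(pixels))
}

#' Cluster pixels by selected edge-energy histogram bins
#'
#' Each selection (one or more bin indices) becomes one cluster; unselected
#' pixels stay unlabeled (0).  The mean normalized XANES of each cluster's
#' member pixels is returned -- grouping pixels of like edge energy and
#' averaging their spectra is the simplest chemically meaningful clustering
#' of the field of view.
#'
#' @param hist Result of [edge_energy_histogram()].
#' @param selections List of integer vectors of bin indices, one per
#'   cluster.
#' @param normalized Normalized `energy_stack` (for cluster mean spectra).
#' @return List: `labels` (`H x W` integer matrix, 0 = unlabeled) and
#'   `mean_spectra` (`n_clusters x n_energies`).
#' @export
cluster_by_edge_energy <- function(hist, selections, normalized) {
  d <- dim(normalized$data)
  labels <- matrix(0L, d[2], d[3])
  Y <- .as_spectra(normalized)
  means <- matrix(NA_real_, length(selections), d[1])
  for (k in seq_along(selections)) {
    px <- unlist(hist$pixels[selections[[k]]], use.names = FALSE)
    if (!length(px)) {
      warning("cluster ", k, " selects empty histogram bin(s)")
      next
    }
    labels[px] <- k
    means[k, ] <- rowMeans(Y[, px, drop = FALSE])
  }
  list(labels = labels, mean_spectra = means)
}

#' Bulk XANES of the field of view
#'
#' Per-energy mean over the (optionally masked) pixels -- equivalent to the
#' bulk absorption spectrum a conventional XAS measurement of the whole
#' field of view would record.
#'
#' @param stack An `energy_stack`.
#' @param mask Optional logical mask of pixels to include.
#' @return Numeric vector, one value per energy.
#' @export
bulk_xanes <- function(stack, mask = NULL) {
  Y <- .as_spectra(stack)
  if (!is.null(mask)) Y <- Y[, as.vector(mask), drop = FALSE]
  if (ncol(Y) == 0) stop("empty selection: no unmasked pixels")
  rowMeans(Y)
}

#' Load and resample reference XANES spectra
#'
#' Reads normalized reference spectra from two-column text files
#' (energy_eV, normalized absorption; whitespace or comma separated,
#' `#` comments allowed) and resamples them onto the stack's energy grid by
#' linear interpolation.  No extrapolation: the grid must lie inside each
#' reference's native range.
#'
#' @param paths Character vector of spectrum files (names become labels),
#'   or a named list of two-column matrices/data frames.
#' @param energies_eV Target energy grid.
#' @return A `reference_set`: list with `names` and `spectra`
#'   (`n_refs x n_energies`).
#' @export
reference_set <- function(paths, energies_eV) {
  read_one <- function(p) {
    if (is.character(p)) {
      tb <- utils::read.table(p, header = FALSE, comment.char = "#",
                              sep = "", fill = TRUE)
      if (ncol(tb) < 2) tb <- utils::read.table(p, header = FALSE, sep = ",",
                                                comment.char = "#")
      tb <- tb[, 1:2]
    } else tb <- as.data.frame(p)[, 1:2]
    names(tb) <- c("E", "mu")
    tb
  }
  items <- if (is.list(paths) && !is.data.frame(paths)) paths else as.list(paths)
  nm <- names(items)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(seq_along(items), function(i) {
      if (is.character(items[[i]]))
        sub("\\.[^.]*$", "", basename(items[[i]])) else paste0("ref", i)
    }, character(1))
  spectra <- t(vapply(items, function(p) {
    tb <- read_one(p)
    if (min(energies_eV) < min(tb$E) || max(energies_eV) > max(tb$E))
      stop("stack energy grid extends beyond a reference's native range; ",
           "no extrapolation is performed")
    stats::approx(tb$E, tb$mu, xout = energies_eV)$y
  }, numeric(length(energies_eV))))
  if (any(!is.finite(spectra))) stop("reference spectra must be finite")
  structure(list(names = nm, spectra = spectra, energies_eV = energies_eV),
            class = "reference_set")
}

# Exact small-scale non-negative least squares by support enumeration:
# for every non-empty subset S of references, the unconstrained LS solution
# restricted to S is computed (vectorized across pixels); among subsets
# whose solution is feasible (all weights >= 0) the smallest residual wins.
# For the <= 4 references typical of LC fitting this is exact and fast.
.nnls_enumerate <- function(R, Y) {
  n_refs <- ncol(R)
  n_pix <- ncol(Y)
  if (n_refs > 8) stop("support enumeration NNLS is limited to 8 references")
  best_rss <- rep(Inf, n_pix)
  W <- matrix(0, n_refs, n_pix)
  yss <- colSums(Y^2)
  subsets <- lapply(seq_len(2^n_refs - 1),
                    function(m) which(bitwAnd(m, 2^(seq_len(n_refs) - 1)) > 0))
  for (S in subsets) {
    RS <- R[, S, drop = FALSE]
    G <- crossprod(RS)
    sol <- tryCatch(solve(G, crossprod(RS, Y)), error = function(e) NULL)
    if (is.null(sol)) next
    feas <- colSums(sol < -1e-12) == 0
    if (!any(feas)) next
    fit <- RS %*% sol
    rss <- yss + colSums(fit^2) - 2 * colSums(fit * Y)
    upd <- feas & rss < best_rss - 1e-15
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      W[, upd] <- 0
      W[S, upd] <- pmax(sol[, upd, drop = FALSE], 0)
    }
  }
  list(weights = W, rss = pmax(best_rss, 0))
}

#' Linear-combination fit of reference spectra to every pixel
#'
#' Solves, for each unmasked pixel, `min_w || mu_n - sum_i w_i r_i ||^2`
#' over the fit window (energies in `[pre_hi, post_hi]`), with `w_i >= 0`
#' by default (set `nonneg = FALSE` for unconstrained least squares).  The
#' fit quality per pixel is the R-factor
#' `R = sum_E (mu_n - fit)^2 / sum_E mu_n^2` on the same window.  Masked
#' pixels get zero weights and `R = NaN`.
#'
#' @param normalized Normalized `energy_stack`.
#' @param refs A [reference_set()] on the same energy grid (>= 2 spectra).
#' @param cfg An [edge_config()] (defines the fit window).
#' @param mask Logical mask of pixels to fit.
#' @param nonneg Constrain weights to be non-negative (default `TRUE`).
#' @return List: `weights` (named list of `H x W` maps, one per reference)
#'   and `rfactor` (`H x W` map).
#' @export
lc_fit <- function(normalized, refs, cfg, mask = NULL, nonneg = TRUE) {
  if (nrow(refs$spectra) < 2) stop("LC fitting requires at least 2 references")
  E <- normalized$energies_eV
  if (!isTRUE(all.equal(refs$energies_eV, E)))
    stop("reference set is not on the stack's energy grid")
  win <- which(E >= cfg$pre_hi & E <= cfg$post_hi)
  R <- t(refs$spectra[, win, drop = FALSE])        # n_win x n_refs
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    dep <- qrR$pivot[(qrR$rank + 1):ncol(R)]
    stop("reference matrix is rank deficient; collinear spectrum: ",
         paste(refs$names[dep], collapse = ", "))
  }
  d <- dim(normalized$data)
  Y <- .as_spectra(normalized)[win, , drop = FALSE]
  sel <- if (is.null(mask)) seq_len(ncol(Y)) else which(as.vector(mask))
  Ys <- Y[, sel, drop = FALSE]
  if (nonneg) {
    fit <- .nnls_enumerate(R, Ys)
    Wm <- fit$weights
    rss <- fit$rss
  } else {
    Wm <- qr.coef(qrR, Ys)
    resid <- Ys - R %*% Wm
    rss <- colSums(resid^2)
  }
  denom <- colSums(Ys^2)
  rfac_sel <- ifelse(denom > 0, rss / denom, NaN)
  rfactor <- matrix(NaN, d[2], d[3])
  rfactor[sel] <- rfac_sel
  weights <- lapply(seq_len(nrow(refs$spectra)), function(i) {
    m <- matrix(0, d[2], d[3])
    m[sel] <- Wm[i, ]
    m
  })
  names(weights) <- refs$names
  list(weights = weights, rfactor = rfactor)
}

#' R-factor of a fit
#'
#' `R = sum((data - fit)^2) / sum(data^2)`: zero iff the fit reproduces the
#' data on the window, invariant under common positive rescaling.
#'
#' @param data,fit Numeric vectors on the fit window.
#' @return The R-factor.
#' @export
rfactor <- function(data, fit) {
  sum((data - fit)^2) / sum(data^2)
}

#' Cluster pixels in the edge-jump vs R-factor plane
#'
#' Plotting each pixel's edge jump against its R-factor exposes pixels with
#' plenty of the edge element (high jump) but a poor fit (high R): the
#' signature of a phase missing from the reference set.  Each supplied
#' rectangle (or polygon) in `(J, R)` space becomes one cluster.
#'
#' @param edge_jump Edge-jump map.
#' @param rfactor_map R-factor map.
#' @param regions List of regions: either `c(jmin, jmax, rmin, rmax)`
#'   rectangles or two-column `(J, R)` polygon vertex matrices.
#' @return Integer `H x W` label map (0 = unlabeled).
#' @export
jump_vs_rfactor_cluster <- function(edge_jump, rfactor_map, regions) {
  labels <- matrix(0L, nrow(edge_jump), ncol(edge_jump))
  J <- as.vector(edge_jump); R <- as.vector(rfactor_map)
  valid <- is.finite(J) & is.finite(R)
  for (k in seq_along(regions)) {
    reg <- regions[[k]]
    inside <- if (is.matrix(reg)) {
      .point_in_polygon(J, R, reg)
    } else {
      J >= reg[1] & J <= reg[2] & R >= reg[3] & R <= reg[4]
    }
    labels[valid & inside] <- k
  }
  labels
}

# Ray-casting point-in-polygon, vectorized over points.
.point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Render an RGB phase map from LC weights
#'
#' Assigns each reference's weight map to a color channel (surplus
#' references are summed into their designated channel), normalizes the
#' channel fractions by the pixel's total weight, and multiplies by the
#' pixel's edge jump scaled to `[0, 1]` (clipped at its 99th percentile,
#' robust to hot pixels).  The edge jump thus acts as a transparency value:
#' strongly absorbing pixels are bright, weakly absorbing (and noisier)
#' pixels fade to black, which is why no additional R-factor filtering is
#' needed.
#'
#' @param weights Named list of weight maps (from [lc_fit()]).
#' @param edge_jump Edge-jump map.
#' @param channels Named list `list(r = ..., g = ..., b = ...)` giving, per
#'   channel, the reference names (or indices) summed into it.  Every
#'   reference must be assigned to exactly one channel.
#' @param mask Logical mask; masked pixels render black.
#' @return `H x W x 3` array with values in `[0, 1]`.
#' @export
rgb_phase_map <- function(weights, edge_jump, channels = NULL, mask = NULL) {
  n_refs <- length(weights)
  if (n_refs < 2) stop("at least 2 reference weight maps are required")
  if (is.null(channels)) {
    channels <- list(r = 1, g = 2,
                     b = if (n_refs >= 3) 3:n_refs else integer(0))
  }
  idx <- lapply(channels[c("r", "g", "b")], function(ch) {
    if (is.character(ch)) match(ch, names(weights)) else as.integer(ch)
  })
  used <- sort(unname(unlist(idx)))
  if (!identical(used, seq_len(n_refs)))
    stop("channel assignment must cover every reference exactly once")
  h <- nrow(edge_jump); w <- ncol(edge_jump)
  chan <- lapply(idx, function(ii) {
    if (!length(ii)) return(matrix(0, h, w))
    Reduce(`+`, weights[ii])
  })
  total <- chan$r + chan$g + chan$b
  pos <- total > 0
  for (nm in c("r", "g", "b")) chan[[nm]][pos] <- chan[[nm]][pos] / total[pos]
  hi <- stats::quantile(edge_jump[is.finite(edge_jump)], 0.99, names = FALSE)
  A <- pmin(pmax(edge_jump / hi, 0), 1)
  A[!is.finite(A)] <- 0
  if (!is.null(mask)) A[!mask] <- 0
  out <- array(0, dim = c(h, w, 3))
  out[, , 1] <- chan$r * A
  out[, , 2] <- chan$g * A
  out[, , 3] <- chan$b * A
  out
}

#' Run the full XANES analysis pipeline
#'
#' Edge-jump map, noise filter, normalization (+ slope filter), edge-energy
#' map, and -- when references are given -- LC fitting, R-factor map and
#' RGB phase map.
#'
#' @param stack Aligned OD `energy_stack`.
#' @param cfg An [edge_config()].
#' @param refs Optional [reference_set()].
#' @param channels Optional channel assignment for [rgb_phase_map()].
#' @return A `xanes_result` list: `edge_jump`, `noise_mask`, `norm_mask`,
#'   `combined_mask`, `normalized`, `edge_energy`, and (with references)
#'   `weights`, `rfactor`, `rgb`.
#' @export
xanes_analyze <- function(stack, cfg, refs = NULL, channels = NULL) {
  jump <- edge_jump_map(stack, cfg)
  nmask <- noise_filter(stack, cfg, jump = jump)
  norm <- normalize_stack(stack, cfg, mask = nmask)
  ee <- edge_energy_map(norm$normalized, cfg, mask = norm$combined_mask)
  res <- list(edge_jump = jump, noise_mask = nmask,
              norm_mask = norm$norm_mask,
              combined_mask = norm$combined_mask,
              normalized = norm$normalized, edge_energy = ee)
  if (!is.null(refs)) {
    fit <- lc_fit(norm$normalized, refs, cfg, mask = norm$combined_mask)
    res$weights <- fit$weights
    res$rfactor <- fit$rfactor
    res$rgb <- rgb_phase_map(fit$weights, jump, channels,
                             mask = norm$combined_mask)
  }
  class(res) <- "xanes_result"
  res
}
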