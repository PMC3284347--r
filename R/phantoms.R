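#' @title Synthetic phantoms with ground truth
#' @description Generators that emulate every input the pipeline consumes --
#'   XANES energy stacks, mosaic tile sets, tomographic projection series --
#'   as pure functions of their parameters and a seed, returning the ground
#'   truth alongside the data so recovery can be measured exactly.  They
#'   model the dominant degradations of real TXM data (stage jitter,
#'   vignetting, Gaussian OD noise, per-pixel baselines) but not partial
#'   coherence or zone-plate point-spread effects.
#' @name phantoms
NULL

# Run fn with a private RNG stream; the caller's RNG state is untouched.
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

# Modified Shepp-Logan ellipse table: value, a, b, x0, y0, phi_deg
.shepp_logan_ellipses <- matrix(c(
   1.0, 0.69,   0.92,   0,     0,      0,
  -0.8, 0.6624, 0.8740, 0,    -0.0184, 0,
  -0.2, 0.11,   0.31,   0.22,  0,    -18,
  -0.2, 0.16,   0.41,  -0.22,  0,     18,
   0.1, 0.21,   0.25,   0,     0.35,   0,
   0.1, 0.046,  0.046,  0,     0.1,    0,
   0.1, 0.046,  0.046,  0,    -0.1,    0,
   0.1, 0.046,  0.023, -0.08, -0.605,  0,
   0.1, 0.023,  0.023,  0,    -0.606,  0,
   0.1, 0.023,  0.046,  0.06, -0.605,  0), ncol = 6, byrow = TRUE)

#' Modified Shepp-Logan head phantom
#'
#' The classic 10-ellipse tomography fixture with contrast-stretched
#' intensities in `[0, 1]`.  Pixels are area-sampled (`oversample^2`
#' sub-samples per pixel), giving the partial-volume ellipse edges a real
#' detector would record; set `oversample = 1` for hard binary edges.
#'
#' @param n Grid size (n x n).
#' @param oversample Sub-sampling factor per axis (default 4).
#' @return Numeric `n x n` matrix, maximum 1.
#' @export
make_shepp_logan <- function(n, oversample = 4) {
  stopifnot(n >= 1, oversample >= 1)
  m <- n * oversample
  # x right, y up on [-1, 1]^2; row = -y, col = x
  ax <- if (m == 1) 0 else seq(-1, 1, length.out = m)
  x <- rep(ax, each = m)
  y <- rep(rev(ax), times = m)
  img <- numeric(m * m)
  for (i in seq_len(nrow(.shepp_logan_ellipses))) {
    e <- .shepp_logan_ellipses[i, ]
    th <- e[6] * pi / 180
    xr <- (x - e[4]) * cos(th) + (y - e[5]) * sin(th)
    yr <- -(x - e[4]) * sin(th) + (y - e[5]) * cos(th)
    img <- img + e[1] * ((xr / e[2])^2 + (yr / e[3])^2 <= 1)
  }
  img <- matrix(img, m, m)
  if (oversample == 1) return(img)
  out <- matrix(0, n, n)
  for (i in seq_len(oversample)) for (j in seq_len(oversample))
    out <- out + img[seq(i, m, by = oversample), seq(j, m, by = oversample)]
  out / oversample^2
}

#' Default XANES phantom description
#'
#' The stated world of the XANES tests: a 128 x 128 field of view scanned
#' at 50 energies across an Fe-K-like edge (7080-7200 eV), three chemical
#' phases with arctangent edge profiles at 7118 / 7123 / 7128 eV (2 eV
#' width), pure-phase disks plus a mixed-phase block, a smooth thickness
#' map, per-pixel linear baselines with slopes up to 0.002 OD/eV and
#' additive Gaussian OD noise.
#'
#' @param H,W Field-of-view size in pixels.
#' @param energies_eV Scan grid.
#' @param e_half Per-phase half-height edge energies, eV (oxidation-state
#'   shifts of a few eV, as observed between Fe phases).
#' @param edge_width_eV Arctangent width parameter, eV.
#' @param white_line Per-phase white-line amplitude (resonance peak just
#'   above the edge) -- the shape feature that distinguishes reference
#'   spectra beyond their edge position.
#' @param noise_sigma Gaussian OD noise standard deviation.
#' @param baseline_slope_max Maximum per-pixel baseline slope, OD/eV.
#'   Baseline slopes are carried by the specimen (scattering and off-edge
#'   absorption scale with thickness); empty pixels keep only a small
#'   detector drift.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return An object of class `xanes_phantom` (parameter bundle for
#'   [make_xanes_stack()]).
#' @export
xanes_phantom <- function(H = 128, W = 128,
                          energies_eV = seq(7080, 7200, length.out = 50),
                          e_half = c(7116, 7123, 7130),
                          edge_width_eV = 2,
                          white_line = c(0.35, 0.15, 0),
                          noise_sigma = 0.05,
                          baseline_slope_max = 0.002,
                          seed = 1) {
  structure(list(H = H, W = W, energies_eV = energies_eV, e_half = e_half,
                 edge_width_eV = edge_width_eV, white_line = white_line,
                 noise_sigma = noise_sigma,
                 baseline_slope_max = baseline_slope_max, seed = seed),
            class = "xanes_phantom")
}

#' Default edge configuration matching the XANES phantom
#'
#' Pre-edge 7080-7110 eV, post-edge 7150-7200 eV, nominal edge 7125 eV,
#' noise factor `k = 3`, default slope thresholds.
#'
#' @param k Noise-filter multiplier.
#' @return An [edge_config()].
#' @export
phantom_edge_config <- function(k = 3) {
  edge_config(pre_lo = 7080, pre_hi = 7110, post_lo = 7150, post_hi = 7200,
              E0 = 7125, k = k)
}

.arctan_profile <- function(E, e_half, width, white_line = 0) {
  0.5 + atan((E - e_half) / width) / pi +
    white_line * exp(-(E - e_half - 8)^2 / (2 * 4^2))
}

.phantom_profiles <- function(p) {
  vapply(seq_along(p$e_half),
         function(i) .arctan_profile(p$energies_eV, p$e_half[i],
                                     p$edge_width_eV, p$white_line[i]),
         numeric(length(p$energies_eV)))
}

#' Generate a synthetic XANES energy stack with ground truth
#'
#' Measurement model, per pixel p and energy E:
#' `OD(E, p) = thickness(p) * sum_i w_i(p) * profile_i(E) + b0(p) +
#' b1(p) * (E - mean(E)) + noise`.  The scene holds one pure-phase disk per
#' phase, a block mixing phases 1 and 2 with a left-to-right gradient, and
#' empty background; the thickness map is a smooth radial dome.  The truth
#' bundle carries everything needed to score recovery: weight maps, the
#' noiseless half-height edge-energy map, the noiseless edge-jump map, the
#' support mask, normalized reference spectra for each phase (computed from
#' noiseless pure-phase spectra) and the matching [edge_config()].
#'
#' @param phantom An [xanes_phantom()].
#' @return List: `stack` (an OD `energy_stack`) and `truth`.
#' @export
make_xanes_stack <- function(phantom = xanes_phantom()) {
  p <- phantom
  H <- p$H; W <- p$W; E <- p$energies_eV
  nE <- length(E); nP <- length(p$e_half)
  profiles <- .phantom_profiles(p)                     # nE x nP
  rr <- rep(seq_len(H), times = W) / H
  cc <- rep(seq_len(W), each = H) / W
  disk <- function(r0, c0, rad) (rr - r0)^2 + (cc - c0)^2 <= rad^2
  wmap <- matrix(0, nP, H * W)
  wmap[1, disk(0.30, 0.30, 0.16)] <- 1
  wmap[2, disk(0.30, 0.70, 0.16)] <- 1
  if (nP >= 3) wmap[3, disk(0.70, 0.30, 0.16)] <- 1
  block <- rr >= 0.55 & rr <= 0.85 & cc >= 0.55 & cc <= 0.85
  u <- (cc - 0.55) / 0.30
  wmap[1, block] <- 0.2 + 0.6 * u[block]
  wmap[2, block] <- 1 - wmap[1, block]
  support <- colSums(wmap) > 0
  thickness <- (0.9 + 0.5 * (1 - ((rr - 0.5)^2 + (cc - 0.5)^2) * 2)) * support
  clean <- profiles %*% (wmap * rep(thickness, each = nP))   # nE x npix
  out <- .with_seed(p$seed, function() {
    b0 <- stats::runif(H * W, 0, 0.1)
    # specimen-borne baseline slope (scales with thickness); bare detector
    # drift of up to 2e-4 OD/eV elsewhere
    b1 <- stats::runif(H * W, -p$baseline_slope_max, p$baseline_slope_max) *
      (thickness / max(thickness)) +
      stats::runif(H * W, -2e-4, 2e-4)
    baseline <- outer(E - mean(E), b1) + rep(b0, each = nE)
    noise <- matrix(stats::rnorm(nE * H * W, 0, p$noise_sigma), nE)
    list(baseline = baseline, noise = noise)
  })
  data <- clean + out$baseline + out$noise
  stack <- energy_stack(array(data, dim = c(nE, H, W)), E, corrected = TRUE)
  cfg <- phantom_edge_config()
  # noiseless stack (with baselines) defines the analytic truth maps
  clean_stack <- energy_stack(array(clean + out$baseline, dim = c(nE, H, W)),
                              E, corrected = TRUE)
  norm0 <- normalize_stack(clean_stack, cfg,
                           mask = matrix(support, H, W))
  truth <- list(
    weights = array(t(wmap), dim = c(H, W, nP)),
    thickness = matrix(thickness, H, W),
    support = matrix(support, H, W),
    e_half_map = edge_energy_map(norm0$normalized, cfg,
                                 mask = matrix(support, H, W)),
    edge_jump = edge_jump_map(clean_stack, cfg),
    refs = .phantom_reference_set(p, cfg),
    cfg = cfg)
  list(stack = stack, truth = truth)
}

# Normalized reference spectrum of each pure phase: the noiseless spectrum
# of a unit-thickness pure pixel run through the same normalization.
.phantom_reference_set <- function(p, cfg) {
  E <- p$energies_eV
  nE <- length(E); nP <- length(p$e_half)
  pure <- .phantom_profiles(p)
  st <- energy_stack(array(pure, dim = c(nE, 1, nP)), E, corrected = TRUE)
  norm <- normalize_stack(st, cfg)
  refs <- matrix(.as_spectra(norm$normalized), nE, nP)
  structure(list(names = paste0("phase", seq_len(nP)),
                 spectra = t(refs), energies_eV = E),
            class = "reference_set")
}

#' Cut a master image into overlapping mosaic tiles with known truth
#'
#' Tiles are cut from `master` on a regular grid with the requested
#' overlap; the *true* cut positions are jittered by integer offsets
#' uniform in `[-jitter_px, jitter_px]` while the motor metadata encodes
#' the nominal (un-jittered) positions -- exactly the situation the
#' stitcher has to fix.  Radial vignetting (darker tile corners, the
#' motivation for feathered blending) and Gaussian noise can be added.
#'
#' @param master 2D numeric matrix.
#' @param grid `c(rows, cols)` tile grid.
#' @param overlap_frac Design overlap fraction.
#' @param jitter_px Maximum absolute positioning error, px.
#' @param vignette_strength Relative corner darkening in `[0, 1)`.
#' @param noise_sigma Additive Gaussian noise sd.
#' @param pixel_size_nm Pixel size encoded in the tile metadata.
#' @param seed Integer seed.
#' @return List: `tiles` (list of [image_frame()]s), `truth_offsets`
#'   (`n x 2` true (row, col) pixel offsets), `nominal_px`.
#' @export
make_mosaic_tiles <- function(master, grid = c(2, 2), overlap_frac = 0.2,
                              jitter_px = 0, vignette_strength = 0,
                              noise_sigma = 0, pixel_size_nm = 50, seed = 1) {
  H <- nrow(master); W <- ncol(master)
  gr <- grid[1]; gc <- grid[2]
  th <- if (gr == 1) H else floor(H / (gr - (gr - 1) * overlap_frac))
  tw <- if (gc == 1) W else floor(W / (gc - (gc - 1) * overlap_frac))
  nom_r <- if (gr == 1) 0 else round(seq(0, H - th, length.out = gr))
  nom_c <- if (gc == 1) 0 else round(seq(0, W - tw, length.out = gc))
  nominal <- cbind(row = rep(nom_r, each = gc), col = rep(nom_c, times = gr))
  n <- gr * gc
  .with_seed(seed, function() {
    jit <- matrix(round(stats::runif(2 * n, -jitter_px, jitter_px)), n, 2)
    truth <- nominal + jit
    truth[, 1] <- pmin(pmax(truth[, 1], 0), H - th)
    truth[, 2] <- pmin(pmax(truth[, 2], 0), W - tw)
    dv <- sqrt(outer(((seq_len(th) - (th + 1) / 2) / (th / 2))^2,
                     ((seq_len(tw) - (tw + 1) / 2) / (tw / 2))^2, "+"))
    vig <- 1 - vignette_strength * (dv / max(dv))^2
    tiles <- lapply(seq_len(n), function(k) {
      px <- master[truth[k, 1] + seq_len(th), truth[k, 2] + seq_len(tw)]
      px <- px * vig
      if (noise_sigma > 0)
        px <- px + matrix(stats::rnorm(th * tw, 0, noise_sigma), th, tw)
      image_frame(px,
                  motor_x_um = nominal[k, 2] * pixel_size_nm / 1000,
                  motor_y_um = nominal[k, 1] * pixel_size_nm / 1000,
                  pixel_size_nm = pixel_size_nm)
    })
    list(tiles = tiles, truth_offsets = truth, nominal_px = nominal)
  })
}

#' Generate a tomographic projection series with known jitter
#'
#' Forward-projects a phantom at the requested angles and degrades the
#' projections with per-angle translations (stage jitter, uniform in
#' `[-jitter_px, jitter_px]` per axis) and Gaussian noise.  A 2D phantom is
#' extruded along the slice axis with a smooth intensity profile so the
#' frames carry 2D structure; a 3D array `(n_slices, n, n)` is projected
#' slice by slice.
#'
#' @param phantom 2D `n x n` matrix or 3D `(n_slices, n, n)` array.
#' @param angles_deg Projection angles.
#' @param jitter_px Maximum absolute per-angle shift, px.
#' @param noise_sigma Additive Gaussian noise sd.
#' @param n_slices Number of slice rows when extruding a 2D phantom.
#' @param seed Integer seed.
#' @return List: `series` (a `projection_series` of `(n_angles, n_slices,
#'   n)` frames), `truth_jitter` (`n_angles x 2` of (dy, dx)), and `clean`
#'   (the jitter/noise-free series).
#' @export
make_projection_series <- function(phantom, angles_deg, jitter_px = 0,
                                   noise_sigma = 0, n_slices = 32, seed = 1) {
  if (length(dim(phantom)) == 2) {
    # specimen occupies the middle of the slice range; frames fade to ~0 at
    # the top/bottom rows as they would with empty space around the sample
    zprof <- 0.02 + 0.98 * exp(-((seq_len(n_slices) - n_slices / 2)^2) /
                                 (2 * (n_slices / 6)^2))
    sino <- forward_project(phantom, angles_deg)
    na <- length(angles_deg)
    w <- ncol(phantom)
    clean <- array(0, dim = c(na, n_slices, w))
    for (a in seq_len(na)) clean[a, , ] <- outer(zprof, sino$data[a, ])
  } else {
    ns <- dim(phantom)[1]
    na <- length(angles_deg)
    w <- dim(phantom)[3]
    clean <- array(0, dim = c(na, ns, w))
    for (s in seq_len(ns)) {
      sino <- forward_project(phantom[s, , ], angles_deg)
      for (a in seq_len(na)) clean[a, s, ] <- sino$data[a, ]
    }
  }
  .with_seed(seed, function() {
    na <- dim(clean)[1]
    jit <- matrix(stats::runif(2 * na, -jitter_px, jitter_px), na, 2)
    if (jitter_px == 0) jit[] <- 0
    data <- clean
    for (a in seq_len(na)) {
      if (max(abs(jit[a, ])) > 0)
        data[a, , ] <- translate_image(clean[a, , ], -jit[a, 1], -jit[a, 2])
      if (noise_sigma > 0)
        data[a, , ] <- data[a, , ] + matrix(stats::rnorm(prod(dim(clean)[2:3]),
                                                         0, noise_sigma),
                                            dim(clean)[2], dim(clean)[3])
    }
    list(series = projection_series(data, angles_deg),
         truth_jitter = jit,
         clean = projection_series(clean, angles_deg))
  })
}
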