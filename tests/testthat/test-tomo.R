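test_that("forward projection: zeros, symmetry, chord length", {
  z <- forward_project(matrix(0, 32, 32), c(0, 45, 90))
  expect_equal(max(abs(z$data)), 0)
  # centered disk: projections are angle-independent up to sampling error,
  # and exactly equal under 90-degree rotations (pure grid permutations)
  n <- 128
  rr <- outer(seq_len(n) - (n + 1) / 2, rep(1, n)); cc <- t(rr)
  disk <- (rr^2 + cc^2 <= 30^2) * 1
  sg <- forward_project(disk, c(0, 90, 180, 270))
  expect_equal(sg$data[1, ], sg$data[2, ], tolerance = 1e-9)
  expect_equal(sg$data[1, ], sg$data[3, ], tolerance = 1e-9)
  sga <- forward_project(disk, seq(0, 170, by = 10))
  expect_lt(max(apply(sga$data, 2, stats::sd)) / max(sga$data), 0.02)
  # central ray integrates the full chord, 2r
  expect_equal(sga$data[1, 64], 60, tolerance = 0.02 * 60)
  expect_error(forward_project(matrix(0, 4, 8), 0), "square")
})

test_that("FBP reconstructs Shepp-Logan and single points", {
  expect_equal(max(abs(fbp_reconstruct(sinogram(matrix(0, 90, 32),
                                                seq(0, 178, by = 2))))), 0)
  ph <- make_shepp_logan(128)
  sg <- forward_project(ph, seq(0, 179, by = 1))
  rec <- fbp_reconstruct(sg)
  expect_lt(sqrt(mean((rec - ph)^2)), 0.05)
  # impulse response peaks at the right pixel
  imp <- matrix(0, 64, 64); imp[20, 40] <- 1
  reci <- fbp_reconstruct(forward_project(imp, seq(0, 179, by = 2)))
  expect_equal(as.vector(arrayInd(which.max(reci), dim(reci))), c(20, 40))
  # linearity
  rec2 <- fbp_reconstruct(sinogram(2 * sg$data, sg$angles_deg))
  expect_equal(rec2, 2 * rec, tolerance = 1e-10)
  # limited angular span warns but still runs
  expect_warning(fbp_reconstruct(sinogram(sg$data[1:60, ],
                                          sg$angles_deg[1:60])),
                 "limited-angle")
})

test_that("ROI reconstruction equals the cropped full reconstruction", {
  ph <- make_shepp_logan(64)
  sg <- forward_project(ph, seq(0, 176, by = 4))
  full <- fbp_reconstruct(sg)
  roi <- fbp_reconstruct(sg, roi = c(17, 25, 32, 32))
  expect_equal(dim(roi), c(32, 32))
  expect_equal(roi, full[17:48, 25:56], tolerance = 1e-6)
})

test_that("forward/inverse consistency on Shepp-Logan", {
  ph <- make_shepp_logan(128)
  sg <- forward_project(ph, seq(0, 179, by = 1))
  rec <- fbp_reconstruct(sg)
  resg <- forward_project(rec, sg$angles_deg)
  rel <- sqrt(sum((resg$data - sg$data)^2) / sum(sg$data^2))
  expect_lt(rel, 0.10)
})

test_that("ART converges on consistent data and beats FBP at sparse views", {
  expect_error(art_reconstruct(sinogram(matrix(0, 4, 4), 1:4), n_iter = 0),
               "n_iter")
  expect_error(art_reconstruct(sinogram(matrix(0, 4, 4), 1:4), relax = 0),
               "relax")
  imp <- matrix(0, 32, 32); imp[10, 20] <- 1
  sgi <- forward_project(imp, seq(0, 170, by = 10))
  ra <- art_reconstruct(sgi, n_iter = 30, relax = 1)
  res <- attr(ra, "residuals")
  expect_lt(res[length(res)], 0.06)
  expect_true(all(diff(res) < 1e-9))            # monotone convergence here
  # sparse-view comparison: 45 views over 180 degrees
  ph <- make_shepp_logan(64)
  sg <- forward_project(ph, seq(0, 176, by = 4))
  rec_art <- art_reconstruct(sg, n_iter = 20, relax = 0.25, nonneg = TRUE)
  rec_fbp <- fbp_reconstruct(sg)
  expect_lt(sqrt(mean((rec_art - ph)^2)), sqrt(mean((rec_fbp - ph)^2)))
  # dense-angle agreement between the two algorithms (FBP needs the finer
  # grid to get its discretization error below the 0.05 band)
  ph128 <- make_shepp_logan(128)
  sgd <- forward_project(ph128, seq(0, 178, by = 2))
  agree <- sqrt(mean((art_reconstruct(sgd, n_iter = 5, relax = 0.5) -
                        fbp_reconstruct(sgd))^2))
  expect_lt(agree, 0.05)
})

test_that("volume reconstruction is separable and validates frames", {
  ph <- make_shepp_logan(32)
  sim <- make_projection_series(ph, seq(0, 176, by = 4), n_slices = 3, seed = 2)
  vol <- reconstruct_volume(sim$series, "fbp")
  for (s in 1:3) {
    sg <- sinogram(sim$series$data[, s, ], sim$series$angles_deg)
    expect_identical(vol[s, , ], fbp_reconstruct(sg))
  }
  volr <- reconstruct_volume(sim$series, "fbp", roi = c(1, 1, 16, 16))
  expect_equal(dim(volr), c(3, 16, 16))
  bad <- sim$series
  bad$data[2, 1, 1] <- NaN
  expect_error(reconstruct_volume(bad, "fbp"), "angle 4")
})

test_that("rotation center is found to subpixel accuracy", {
  ph <- make_shepp_logan(64)
  sg <- forward_project(ph, seq(0, 179, by = 1))
  expect_lt(abs(find_rotation_center(sg) - 32.5), 0.25)
  # sinogram shifted 2 px off axis
  sh <- sg
  sh$data <- cbind(sg$data[, 3:64], matrix(0, nrow(sg$data), 2))
  expect_lt(abs(find_rotation_center(sh) - 30.5), 0.3)
  # 90-degree span: fallback with warning
  expect_warning(ctr <- find_rotation_center(
    sinogram(sg$data[1:90, ], sg$angles_deg[1:90])), "geometric center")
  expect_equal(ctr, 32.5)
})

test_that("jitter correction recovers injected shifts", {
  ph <- make_shepp_logan(64)
  ang <- seq(0, 178, by = 2)
  # zero injected jitter: corrections stay small
  sim0 <- make_projection_series(ph, ang, jitter_px = 0, n_slices = 48,
                                 seed = 7)
  jc0 <- jitter_correct(sim0$series)
  expect_lt(max(abs(as.matrix(jc0$shifts[, c("dy", "dx")]))), 0.3)
  # +-3 px i.i.d. jitter recovered within 0.5 px RMS
  sim <- make_projection_series(ph, ang, jitter_px = 3, n_slices = 48,
                                seed = 7)
  jc <- jitter_correct(sim$series)
  err <- as.matrix(jc$shifts[, c("dy", "dx")]) - sim$truth_jitter
  expect_lt(sqrt(mean(err^2)), 0.5)
  # single projection: no-op
  one <- projection_series(sim$series$data[1, , , drop = FALSE], 0)
  jc1 <- jitter_correct(one)
  expect_equal(unlist(jc1$shifts[, c("dy", "dx")]), c(dy = 0, dx = 0))
})

test_that("template tracking follows a feature box", {
  ph <- make_shepp_logan(64)
  ang <- c(0, 1, 2, 3)           # tight span: negligible scene rotation
  sim <- make_projection_series(ph, ang, jitter_px = 0, n_slices = 48,
                                seed = 3)
  data <- sim$series$data
  inj <- cbind(c(0, 3, -2, 4), c(0, -1, 2, -3))
  for (i in 2:4) data[i, , ] <- translate_image(sim$series$data[i, , ],
                                                -inj[i, 1], -inj[i, 2])
  ser <- projection_series(data, ang)
  jc <- jitter_correct(ser, method = "template", box = c(16, 20, 16, 24),
                       detrend = "poly", detrend_order = 0)
  rec <- as.matrix(jc$shifts[, c("dy", "dx")])
  err <- rec - sweep(inj, 2, colMeans(inj))   # constant offset is detrended
  expect_lt(max(abs(err)), 0.75)
})
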