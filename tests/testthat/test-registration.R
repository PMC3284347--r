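test_that("zone-plate focal length follows f = D*dr/lambda", {
  zp <- zone_plate(60, 30)
  expect_equal(zp$N, 500)
  # lambda(6500 eV) = 1239.842/6500 = 0.190745 nm; f = 60e3*30/lambda nm
  expect_equal(zp_focal_length(zp, 6500), 9.43668, tolerance = 1e-5)
  # f linear in E
  E <- seq(5000, 12000, by = 500)
  f <- zp_focal_length(zp, E)
  expect_equal(zp_focal_length(zp, 13000), 2 * zp_focal_length(zp, 6500))
  expect_lt(max(abs(diff(f, differences = 2))), 1e-12)
  expect_error(zp_focal_length(zp, -1), "energy")
})

test_that("magnification solves the fixed-distance thin lens and decreases with energy", {
  zp <- zone_plate(60, 30)
  g <- txm_geometry(1000)
  # hand-solved quadratic: f = 9.436 mm, L = 1000 mm -> u ~ 9.526, M ~ 103.97
  expect_equal(magnification(zp, g, 6500), 103.96, tolerance = 1e-3)
  E <- seq(6000, 9000, by = 100)
  M <- vapply(E, function(e) magnification(zp, g, e), numeric(1))
  expect_true(all(diff(M) < 0))
  expect_true(all(M > 1))
  # f >= L/4 has no magnifying solution
  expect_error(magnification(zp, txm_geometry(4 * zp_focal_length(zp, 6500)),
                             6500), "no real focus")
})

test_that("rescale_to_reference is identity at equal M and scales features", {
  img <- textured_phantom(64)
  expect_equal(rescale_to_reference(img, 100, 100), img, tolerance = 1e-12)
  # a centered 2 px bar magnified 2x becomes ~4 px wide
  bar <- matrix(0, 33, 33); bar[, 16:17] <- 1
  big <- rescale_to_reference(bar, 1, 2)
  width <- sum(colMeans(big) > 0.5)
  expect_true(abs(width - 4) <= 1)
  # round trip s then 1/s holds for band-limited content (white-noise
  # texture would be lost to the low-pass of downscaling)
  g <- seq(0, 4 * pi, length.out = 64)
  smooth <- outer(sin(g), cos(1.5 * g)) + outer(g / 10, g / 12)
  sc <- rescale_to_reference(smooth, 1, 1.3)
  back <- rescale_to_reference(sc, 1.3, 1)
  core <- 10:55
  expect_lt(max(abs((back - smooth)[core, core])), 0.02 * diff(range(smooth)))
  expect_error(rescale_to_reference(img, 1, 3), "outside")
})

test_that("phase correlation recovers integer circular shifts exactly", {
  img <- textured_phantom(64)
  mov <- img[((seq_len(64) - 1 - 5) %% 64) + 1, ((seq_len(64) - 1 + 3) %% 64) + 1]
  s <- phase_correlate(img, mov, window = FALSE)
  expect_equal(c(s$dy, s$dx), c(5, -3), tolerance = 1e-9)
  expect_gt(s$peak_quality, 0.9)
  s0 <- phase_correlate(img, img)
  expect_equal(c(s0$dy, s0$dx), c(0, 0), tolerance = 1e-9)
  expect_gt(s0$peak_quality, 0.8)
  expect_error(phase_correlate(matrix(1, 8, 8), matrix(2, 8, 8)),
               "no spectral content")
})

test_that("phase correlation resolves subpixel shifts and is antisymmetric", {
  img <- textured_phantom(64)
  N <- 64
  k <- c(0:(N / 2), (-N / 2 + 1):-1)
  ph <- exp(-2i * pi * outer(k, rep(1, N)) * 2.5 / N)
  mov <- Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / N^2
  s <- phase_correlate(img, mov)
  expect_true(s$dy >= 2.3 && s$dy <= 2.7)
  expect_lt(abs(s$dx), 0.1)
  # antisymmetry on a non-degenerate pair
  mov2 <- img[((seq_len(64) - 1 - 7) %% 64) + 1, ]
  a <- phase_correlate(img, mov2)
  b <- phase_correlate(mov2, img)
  expect_lt(abs(a$dy + b$dy), 0.1)
  expect_lt(abs(a$dx + b$dx), 0.1)
})

test_that("align_stack recovers injected shifts and is idempotent", {
  base <- textured_phantom(64)
  sh <- cbind(c(0, 3, -2, 5, 1), c(0, -4, 2, 0, -3))
  frames <- array(0, c(5, 64, 64))
  for (i in 1:5) frames[i, , ] <- translate_image(base, -sh[i, 1], -sh[i, 2])
  st <- energy_stack(frames, seq(7100, 7140, by = 10))
  al <- align_stack(st)
  expect_lt(max(abs(as.matrix(al$shifts[, c("dy", "dx")]) - sh)), 0.2)
  al2 <- align_stack(al$stack)
  expect_lt(max(abs(as.matrix(al2$shifts[, c("dy", "dx")]))), 0.5)
  # identical frames -> zero shifts
  same <- array(0, c(3, 64, 64))
  for (i in 1:3) same[i, , ] <- base
  al3 <- align_stack(energy_stack(same, 1:3))
  expect_lt(max(abs(as.matrix(al3$shifts[, c("dy", "dx")]))), 1e-6)
  # single frame -> returns input, one zero shift
  al4 <- align_stack(energy_stack(array(base, c(1, 64, 64)), 7100))
  expect_equal(nrow(al4$shifts), 1)
  expect_equal(unname(unlist(al4$shifts[1, c("dy", "dx")])), c(0, 0))
})

test_that("low-quality frames are flagged, not dropped", {
  base <- textured_phantom(32)
  frames <- array(0, c(2, 32, 32))
  frames[1, , ] <- base
  frames[2, , ] <- matrix(rnorm(32 * 32), 32)   # unrelated content
  st <- energy_stack(frames, c(1, 2))
  expect_warning(al <- align_stack(st, q_min = 0.6), "flagged")
  expect_true(al$shifts$flagged[2])
  expect_equal(n_frames(al$stack), 2)
})

test_that("log-polar stage measures rotation and scale approximately", {
  img <- textured_phantom(128)
  rot <- txmkit:::rotate_image(img, 7)
  rs <- phase_correlate_rotscale(img, rot)
  expect_lt(abs(abs(rs$rotation_deg) - 7), 1.2)
  expect_lt(abs(rs$scale - 1), 0.02)
})
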