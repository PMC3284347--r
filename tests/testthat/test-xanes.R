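cfg0 <- edge_config(pre_lo = 7080, pre_hi = 7110, post_lo = 7150,
                    post_hi = 7200, E0 = 7125, k = 3)
E50 <- seq(7080, 7200, length.out = 50)

test_that("edge_config enforces window ordering", {
  expect_error(edge_config(7100, 7090, 7150, 7200, 7125), "pre_lo")
  expect_error(edge_config(7080, 7110, 7150, 7200, 7125, k = 0), "k must")
})

test_that("edge jump is post mean minus pre mean and scales with thickness", {
  # constant spectrum -> 0; unit step -> 1
  flat <- stack_from_spectra(matrix(0.7, 50, 1), E50)
  expect_equal(edge_jump_map(flat, cfg0)[1, 1], 0)
  step <- stack_from_spectra(matrix(as.numeric(E50 > 7125), 50, 1), E50)
  expect_equal(edge_jump_map(step, cfg0)[1, 1], 1)
  # thickness scaling a fixed edge profile: J strictly proportional
  prof <- 0.5 + atan((E50 - 7123) / 2) / pi
  thick <- seq(0.2, 2, length.out = 200)
  stt <- stack_from_spectra(outer(prof, thick), E50)
  Jt <- as.vector(edge_jump_map(stt, cfg0))
  expect_gt(stats::cor(Jt, thick), 0.999)
  expect_lt(max(abs(Jt / thick - Jt[1] / thick[1])), 1e-9)
  # on the full phantom the per-pixel baseline slopes jitter J, but the
  # correlation with areal concentration remains strong
  ph <- make_xanes_stack(xanes_phantom(H = 48, W = 48, noise_sigma = 0,
                                       baseline_slope_max = 2e-4, seed = 3))
  J <- edge_jump_map(ph$stack, cfg0)
  sup <- ph$truth$support
  eff <- ph$truth$thickness * apply(ph$truth$weights, c(1, 2), sum)
  expect_gt(stats::cor(J[sup], eff[sup]), 0.9)
  # too-narrow window errors
  bad <- edge_config(7080, 7081, 7150, 7200, 7125)
  expect_error(edge_jump_map(step, bad), "at least 2")
})

test_that("noise filter thresholds jump against k * pre-edge sd", {
  # two pixels with identical pre-edge noise (sd known), different jumps
  pre_idx <- which(E50 >= 7080 & E50 <= 7110)
  spec <- matrix(0, 50, 2)
  wiggle <- rep_len(c(-0.01, 0.01), length(pre_idx))   # sd ~ 0.0104
  spec[pre_idx, 1] <- wiggle; spec[pre_idx, 2] <- wiggle
  s <- stats::sd(wiggle)
  spec[E50 >= 7150, 1] <- 3.5 * s       # above 3*sd -> kept
  spec[E50 >= 7150, 2] <- 2.0 * s       # below -> removed
  st <- stack_from_spectra(spec, E50)
  m <- noise_filter(st, cfg0)
  expect_true(m[1, 1]); expect_false(m[1, 2])
  # pure-noise phantom: k = 3 removes > 95% of pixels
  set.seed(42)
  noise <- matrix(rnorm(50 * 2000, 0, 0.05), 50, 2000)
  mn <- noise_filter(stack_from_spectra(noise, E50), cfg0)
  expect_lt(mean(mn), 0.05)
  # monotone in k: larger k never un-filters
  cfg_lo <- edge_config(7080, 7110, 7150, 7200, 7125, k = 1.5)
  m_lo <- noise_filter(stack_from_spectra(noise, E50), cfg_lo)
  expect_true(all(m_lo | !mn))
})

test_that("normalization maps pre to 0 and post to 1 and filters bad slopes", {
  # ideal step on a sloped baseline
  base <- 0.05 + 0.003 * (E50 - 7100)
  spec <- matrix(base + 0.9 * as.numeric(E50 > 7125), 50, 1)
  st <- stack_from_spectra(spec, E50)
  out <- normalize_stack(st, cfg0)
  mu <- as.vector(out$normalized$data)
  expect_equal(mean(mu[E50 <= 7110]), 0, tolerance = 1e-10)
  expect_equal(mean(mu[E50 >= 7150]), 1, tolerance = 1e-10)
  expect_true(out$norm_mask[1, 1])
  # pre-edge slope 10x the threshold -> masked and zeroed
  spec2 <- cbind(spec, matrix(0.2 * (E50 - 7100) +
                                as.numeric(E50 > 7125), 50, 1))
  out2 <- normalize_stack(stack_from_spectra(spec2, E50), cfg0)
  expect_false(out2$norm_mask[1, 2])
  expect_equal(max(abs(out2$normalized$data[, 1, 2])), 0)
  # combined mask honours the upstream mask
  out3 <- normalize_stack(stack_from_spectra(spec2, E50), cfg0,
                          mask = matrix(c(FALSE, TRUE), 1, 2))
  expect_equal(as.vector(out3$combined_mask), c(FALSE, FALSE))
})

test_that("half-height edge energy interpolates the first upward crossing", {
  # two points bracketing 0.5 symmetrically -> midpoint
  E <- c(7100, 7110, 7120, 7121, 7130, 7140, 7160, 7180)
  cfg <- edge_config(7090, 7111, 7129, 7181, 7125)
  spec <- matrix(c(0, 0, 0.4, 0.6, 1, 1, 1, 1), length(E), 1)
  st <- stack_from_spectra(spec, E)
  expect_equal(edge_energy_map(st, cfg)[1, 1], 7120.5)
  # arctan profile sampled at 0.5 eV: E_half within 0.05 eV of truth.
  # (The residual bias is the linear pre/post lines chasing the arctan's
  # curved tails; it grows with the profile width relative to the windows.)
  Ef <- seq(7080, 7200, by = 0.5)
  cfg_f <- edge_config(7080, 7110, 7150, 7200, 7125)
  prof <- 0.5 + atan((Ef - 7123.3) / 1.5) / pi
  stf <- stack_from_spectra(matrix(prof, length(Ef), 1), Ef)
  nf <- normalize_stack(stf, cfg_f)
  expect_lt(abs(edge_energy_map(nf$normalized, cfg_f)[1, 1] - 7123.3), 0.05)
  # monotonically decreasing spectrum -> NaN
  dec <- stack_from_spectra(matrix(seq(1, 0, length.out = 50), 50, 1), E50)
  expect_true(is.nan(edge_energy_map(dec, cfg0)[1, 1]))
})

test_that("edge-energy histogram bins on the scan grid and tracks pixels", {
  ee <- matrix(c(7120.1, 7120.1, 7127.4, NaN), 2, 2)
  h <- edge_energy_histogram(ee, E50)
  expect_equal(sum(h$counts), 3)
  expect_equal(length(h$pixels), length(h$counts))
  top2 <- order(h$counts, decreasing = TRUE)[1:2]
  expect_setequal(unlist(h$pixels[top2]), c(1, 2, 3))
  step <- stats::median(diff(E50))
  expect_lt(abs(h$mids[top2[1]] - 7120.1), step)
  # all-NaN map: empty histogram, no error
  h0 <- edge_energy_histogram(matrix(NaN, 2, 2), E50)
  expect_equal(length(h0$counts), 0)
})

test_that("edge-energy clustering pools selected bins with mean spectra", {
  ph <- make_xanes_stack(xanes_phantom(H = 48, W = 48, noise_sigma = 0.02,
                                       seed = 8))
  res <- xanes_analyze(ph$stack, ph$truth$cfg)
  h <- edge_energy_histogram(res$edge_energy, ph$stack$energies_eV)
  # selecting every bin labels every valid pixel
  all_cl <- cluster_by_edge_energy(h, list(seq_along(h$counts)),
                                   res$normalized)
  expect_equal(sum(all_cl$labels > 0), sum(is.finite(res$edge_energy)))
  # the two dominant modes give mean spectra close to the generators
  top <- order(h$counts, decreasing = TRUE)[1:2]
  cl <- cluster_by_edge_energy(h, list(top[1], top[2]), res$normalized)
  expect_equal(nrow(cl$mean_spectra), 2)
  win <- ph$stack$energies_eV >= 7110 & ph$stack$energies_eV <= 7150
  best_match <- function(mu) min(vapply(1:3, function(i)
    sqrt(mean((mu[win] - ph$truth$refs$spectra[i, win])^2)), numeric(1)))
  # grid-width bins also catch mixed-block pixels of similar edge energy,
  # so the cluster means match the generators to ~0.05, not noise/sqrt(n)
  expect_lt(best_match(cl$mean_spectra[1, ]), 0.05)
  expect_lt(best_match(cl$mean_spectra[2, ]), 0.05)
  expect_warning(cluster_by_edge_energy(
    h, list(which(h$counts == 0)[1]), res$normalized), "empty")
})

test_that("bulk XANES averages unmasked pixels", {
  spec <- cbind(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  st <- stack_from_spectra(spec, E50)
  expect_equal(bulk_xanes(st), rowMeans(spec))
  expect_equal(bulk_xanes(st, mask = matrix(c(TRUE, FALSE), 1, 2)),
               spec[, 1])
  expect_error(bulk_xanes(st, mask = matrix(FALSE, 1, 2)), "empty selection")
})

test_that("reference spectra load from text and refuse extrapolation", {
  d <- withr::local_tempdir()
  Ef <- seq(7070, 7210, by = 1)
  for (i in 1:2)
    write.table(cbind(Ef, 0.5 + atan((Ef - 7115 - 8 * i) / 2) / pi),
                file.path(d, sprintf("ref%d.txt", i)),
                row.names = FALSE, col.names = FALSE)
  rs <- reference_set(file.path(d, c("ref1.txt", "ref2.txt")), E50)
  expect_equal(rs$names, c("ref1", "ref2"))
  expect_equal(dim(rs$spectra), c(2, 50))
  expect_error(reference_set(file.path(d, "ref1.txt"),
                             seq(7000, 7200, by = 5)), "native range")
})

test_that("LC fitting recovers exact mixtures and the R-factor formula", {
  r1 <- 0.5 + atan((E50 - 7116) / 2) / pi + 0.3 * exp(-(E50 - 7124)^2 / 32)
  r2 <- 0.5 + atan((E50 - 7130) / 2) / pi
  refs <- structure(list(names = c("a", "b"), spectra = rbind(r1, r2),
                         energies_eV = E50), class = "reference_set")
  mix <- stack_from_spectra(cbind(0.3 * r1 + 0.7 * r2), E50)
  fit <- lc_fit(mix, refs, cfg0)
  expect_equal(fit$weights$a[1, 1], 0.3, tolerance = 1e-8)
  expect_equal(fit$weights$b[1, 1], 0.7, tolerance = 1e-8)
  expect_lt(fit$rfactor[1, 1], 1e-15)
  # hand-computed R-factor: data [1,2], fit [1,1] -> (0+1)/(1+4) = 0.2
  expect_equal(rfactor(c(1, 2), c(1, 1)), 0.2)
  # scale invariance
  expect_equal(rfactor(3 * c(1, 2), 3 * c(1, 1)), 0.2)
  # rank-deficient reference matrix errors naming the collinear spectrum
  refs_bad <- structure(list(names = c("a", "a2"), spectra = rbind(r1, r1),
                             energies_eV = E50), class = "reference_set")
  expect_error(lc_fit(mix, refs_bad, cfg0), "collinear")
  refs_one <- structure(list(names = "a", spectra = rbind(r1),
                             energies_eV = E50), class = "reference_set")
  expect_error(lc_fit(mix, refs_one, cfg0), "at least 2")
})

test_that("NNLS weights are non-negative and sum near 1 for true mixtures", {
  ph <- make_xanes_stack(xanes_phantom(H = 48, W = 48, noise_sigma = 0,
                                       seed = 6))
  res <- xanes_analyze(ph$stack, ph$truth$cfg, refs = ph$truth$refs)
  # noiseless empty pixels have ~zero pre-edge sd, so the k*sd threshold
  # cannot reject them; restrict to actual mixtures
  msk <- res$combined_mask & ph$truth$support
  for (w in res$weights) expect_gte(min(w), 0)
  tot <- Reduce(`+`, res$weights)
  expect_gte(min(tot[msk]), 0.98)
  expect_lte(max(tot[msk]), 1.02)
})

test_that("noisy parameter recovery meets the stated bounds", {
  ph <- make_xanes_stack(xanes_phantom(seed = 5))   # 128^2, sigma = 0.05
  res <- xanes_analyze(ph$stack, ph$truth$cfg, refs = ph$truth$refs)
  step <- stats::median(diff(ph$stack$energies_eV))
  ok <- res$combined_mask & is.finite(res$edge_energy) &
    is.finite(ph$truth$e_half_map)
  expect_lt(mean(abs(res$edge_energy - ph$truth$e_half_map)[ok]), step / 2)
  for (i in 1:3) {
    err <- (res$weights[[i]] - ph$truth$weights[, , i])[res$combined_mask]
    expect_lt(sqrt(mean(err^2)), 0.05)
  }
})

test_that("jump/R-factor clustering flags a withheld phase", {
  ph <- make_xanes_stack(xanes_phantom(seed = 2))
  refs2 <- ph$truth$refs
  refs2$spectra <- refs2$spectra[1:2, ]; refs2$names <- refs2$names[1:2]
  res <- xanes_analyze(ph$stack, ph$truth$cfg, refs = refs2)
  p3 <- ph$truth$weights[, , 3] > 0.5 & res$combined_mask
  others <- ph$truth$weights[, , 3] <= 0.5 & res$combined_mask
  # rectangle over high-J, high-R
  lab <- jump_vs_rfactor_cluster(res$edge_jump, res$rfactor,
                                 list(c(0.3, Inf, 0.02, Inf)))
  expect_gt(sum(lab == 1 & p3) / sum(p3), 0.9)
  expect_lt(sum(lab == 1 & others) / sum(others), 0.02)
  # full-plane region captures every valid pixel; empty polygon none
  lab2 <- jump_vs_rfactor_cluster(res$edge_jump, res$rfactor,
                                  list(c(-Inf, Inf, -Inf, Inf)))
  expect_equal(sum(lab2 == 1), sum(is.finite(res$rfactor) &
                                     is.finite(res$edge_jump)))
  poly <- cbind(c(10, 11, 10.5), c(10, 10, 11))    # far away triangle
  lab3 <- jump_vs_rfactor_cluster(res$edge_jump, res$rfactor, list(poly))
  expect_equal(sum(lab3 == 1), 0)
})

test_that("RGB phase maps mix channels and weight by edge jump", {
  w <- list(a = matrix(c(1, 0.5, 0), 1, 3), b = matrix(c(0, 0.5, 0), 1, 3))
  J <- matrix(1, 1, 3)
  rgb <- rgb_phase_map(w, J)
  expect_equal(rgb[1, 1, ], c(1, 0, 0))
  expect_equal(rgb[1, 2, ], c(0.5, 0.5, 0), tolerance = 1e-9)
  # 4 references, two summed into blue: w = (0,0,.2,.3) -> pure blue
  w4 <- list(r1 = matrix(0, 1, 1), r2 = matrix(0, 1, 1),
             r3 = matrix(0.2, 1, 1), r4 = matrix(0.3, 1, 1))
  rgb4 <- rgb_phase_map(w4, matrix(1e6, 1, 1),
                        channels = list(r = 1, g = 2, b = c(3, 4)))
  expect_equal(rgb4[1, 1, ], c(0, 0, 1))
  expect_error(rgb_phase_map(w4, matrix(1, 1, 1),
                             channels = list(r = 1, g = 2, b = 3)),
               "cover every reference")
})

test_that("pipeline is deterministic given a seed", {
  a <- make_xanes_stack(xanes_phantom(H = 32, W = 32, seed = 4))
  b <- make_xanes_stack(xanes_phantom(H = 32, W = 32, seed = 4))
  expect_identical(a$stack$data, b$stack$data)
  ra <- xanes_analyze(a$stack, a$truth$cfg, refs = a$truth$refs)
  rb <- xanes_analyze(b$stack, b$truth$cfg, refs = b$truth$refs)
  expect_identical(ra$rfactor, rb$rfactor)
  expect_identical(ra$rgb, rb$rgb)
})
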