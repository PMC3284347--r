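# Shared fixtures, all generated in code.

# Shepp-Logan with a little high-frequency texture so phase correlation has
# spectral content everywhere (a plain phantom has large flat regions).
textured_phantom <- function(n, noise = 0.03, seed = 101) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  make_shepp_logan(n) + noise * matrix(rnorm(n * n), n, n)
}

# Smooth-edged disk indicator (logistic profile), for 2E phantoms.
smooth_disk <- function(n, r0, c0, rad, width = 1.5) {
  rr <- outer(seq_len(n), rep(1, n))
  cc <- t(rr)
  1 / (1 + exp((sqrt((rr - r0)^2 + (cc - c0)^2) - rad) / width))
}

# Tiny energy stack holding explicitly given per-pixel spectra.
# spectra: n_energies x n_pixels matrix; laid out as a 1 x n_pixels image.
stack_from_spectra <- function(spectra, energies) {
  energy_stack(array(spectra, dim = c(nrow(spectra), 1, ncol(spectra))),
               energies, corrected = TRUE)
}

# Evaluate stitched canvas against the master it was cut from; returns RMSE
# over the covered region after removing the (unobservable) global offset.
stitch_rmse <- function(stitched, layout_refined, truth_offsets, master) {
  delta <- round(colMeans(truth_offsets - layout_refined)) +
    apply(round(layout_refined), 2, min)
  img <- stitched$image
  rs <- seq_len(nrow(img)) + delta[1]
  cs <- seq_len(ncol(img)) + delta[2]
  ok <- rs >= 1 & rs <= nrow(master)
  okc <- cs >= 1 & cs <= ncol(master)
  sub <- img[ok, okc]
  valid <- stitched$mask[ok, okc] & is.finite(sub)
  sqrt(mean((sub - master[rs[ok], cs[okc]])[valid]^2))
}
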