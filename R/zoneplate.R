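#' @title Zone-plate optics and magnification correction
#' @description The objective of a transmission X-ray microscope is a Fresnel
#'   zone plate whose focal length depends on the X-ray wavelength,
#'   `f = D * dr / lambda`.  During an energy scan the zone plate is moved to
#'   keep the sample in focus, so the magnification changes with energy and
#'   recorded images must be rescaled to a common magnification before any
#'   pixelwise arithmetic.
#' @name zoneplate
NULL

HC_EV_NM <- 1239.842   # h*c in eV.nm

#' Describe a Fresnel zone plate
#'
#' @param D_um Zone-plate diameter in micrometres (> 0).
#' @param dr_nm Outermost zone width in nanometres (> 0).
#' @return A `zone_plate` object with fields `D_um`, `dr_nm` and the derived
#'   total number of zones `N = D / (4 dr)`.
#' @examples
#' zp <- zone_plate(60, 30)   # N = 500 zones
#' @export
zone_plate <- function(D_um, dr_nm) {
  if (D_um <= 0 || dr_nm <= 0) stop("D_um and dr_nm must be > 0")
  structure(list(D_um = D_um, dr_nm = dr_nm,
                 N = (D_um * 1000) / (4 * dr_nm)),
            class = "zone_plate")
}

#' Describe the imaging geometry
#'
#' @param L_mm Fixed sample-to-detector distance along the optical axis, mm.
#' @return A `txm_geometry` object.
#' @export
txm_geometry <- function(L_mm) {
  if (L_mm <= 0) stop("L_mm must be > 0")
  structure(list(L_mm = L_mm), class = "txm_geometry")
}

#' First-order focal length of a zone plate
#'
#' `f = D * dr / lambda` with `lambda = hc / E`; the focal length is linear
#' in the photon energy.
#'
#' @param zp A [zone_plate()].
#' @param energy_eV Photon energy in eV (> 0).
#' @return Focal length in mm.
#' @export
zp_focal_length <- function(zp, energy_eV) {
  if (any(energy_eV <= 0)) stop("energy_eV must be > 0")
  lambda_nm <- HC_EV_NM / energy_eV
  f_nm <- (zp$D_um * 1000) * zp$dr_nm / lambda_nm
  f_nm * 1e-6
}

#' Magnification at a given energy for a fixed sample-detector distance
#'
#' Thin-lens closure of the zone-plate optic: with the sample-to-detector
#' distance `L` fixed, `1/u + 1/v = 1/f` and `u + v = L`.  The magnifying
#' root `u = (L - sqrt(L^2 - 4 f L)) / 2` is taken and `M = v / u > 1`
#' returned.  A real magnifying focus requires `f < L / 4`.
#'
#' @param zp A [zone_plate()].
#' @param geom A [txm_geometry()].
#' @param energy_eV Photon energy in eV.
#' @return Magnification factor `M > 1`.
#' @export
magnification <- function(zp, geom, energy_eV) {
  f <- zp_focal_length(zp, energy_eV)
  L <- geom$L_mm
  if (f >= L / 4)
    stop("no real focus for this geometry: f = ", signif(f, 6),
         " mm >= L/4 = ", signif(L / 4, 6), " mm")
  u <- (L - sqrt(L^2 - 4 * f * L)) / 2
  v <- L - u
  v / u
}

#' Rescale an image to a reference magnification
#'
#' Resamples the image about its geometric center by the scale factor
#' `s = M_ref / M` using bicubic (Catmull-Rom) interpolation, returning an
#' image of the original shape (edge replication where the shrunk image
#' uncovers the canvas).  Scale factors outside `[0.5, 2]` indicate absurd
#' metadata and are rejected.
#'
#' @param img Numeric matrix.
#' @param M Magnification the image was recorded at.
#' @param M_ref Target (reference) magnification.
#' @return Resampled matrix, same shape as `img`.
#' @export
rescale_to_reference <- function(img, M, M_ref) {
  if (M <= 0 || M_ref <= 0) stop("magnifications must be > 0")
  s <- M_ref / M
  if (s < 0.5 || s > 2)
    stop("scale factor ", signif(s, 4), " outside [0.5, 2]; check metadata")
  if (s == 1) return(img)
  h <- nrow(img); w <- ncol(img)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  rows <- cr + (rep(seq_len(h), times = w) - cr) / s
  cols <- cc + (rep(seq_len(w), each = h) - cc) / s
  matrix(interp_bicubic(img, rows, cols), h, w)
}
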