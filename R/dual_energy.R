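#' @title Dual-energy (2E) elemental difference mapping
#' @description Subtracting an image recorded just below an element's
#'   absorption edge from one recorded just above maps that element: only
#'   the edge element changes its absorption appreciably across the narrow
#'   energy interval, so all other contrast (including fiducial markers such
#'   as Au particles) is suppressed in the difference.  Both frames must be
#'   brought to a common magnification and registered first, which this
#'   module does using the zone-plate model and phase correlation.
#' @name dual_energy
NULL

#' Pair a below-edge and an above-edge frame
#'
#' @param below,above [image_frame()]s recorded below/above the edge, in
#'   optical density after reference correction.
#' @param element Label of the target element (e.g. `"Mn"`).
#' @return A `two_energy_pair` object.
#' @export
two_energy_pair <- function(below, above, element = "") {
  stopifnot(inherits(below, "image_frame"), inherits(above, "image_frame"))
  if (!(above$energy_eV > below$energy_eV))
    stop("above.energy_eV must exceed below.energy_eV")
  if (!identical(dim(below$pixels), dim(above$pixels)))
    stop("paired frames must have identical pixel shape")
  structure(list(below = below, above = above, element = element),
            class = "two_energy_pair")
}

#' Compute a 2E elemental difference map
#'
#' The above-edge frame is rescaled to the below-edge frame's magnification
#' (the below frame is the fixed reference), registered onto it by phase
#' correlation, and subtracted: `map = OD_above - OD_below`.  Positive
#' values indicate the target element; contrast of elements without an edge
#' in the interval largely cancels.
#'
#' @param pair A [two_energy_pair()] of optical-density frames.
#' @param zp A [zone_plate()]; with `geom`, drives the magnification model.
#'   Pass `NULL` to skip magnification correction (frames already scaled).
#' @param geom A [txm_geometry()] or `NULL`.
#' @return Numeric matrix: the elemental difference map in OD units, with
#'   attribute `"shift"` holding the measured alignment.
#' @export
difference_map <- function(pair, zp = NULL, geom = NULL) {
  below <- pair$below$pixels
  above <- pair$above$pixels
  if (!is.null(zp) && !is.null(geom)) {
    M_below <- magnification(zp, geom, pair$below$energy_eV)
    M_above <- magnification(zp, geom, pair$above$energy_eV)
    above <- rescale_to_reference(above, M_above, M_below)
  }
  s <- phase_correlate(below, above)
  above <- translate_image(above, s$dy, s$dx)
  out <- above - below
  attr(out, "shift") <- s
  out
}

#' Compute 2E difference maps for a whole tomographic series
#'
#' Applies [difference_map()] angle by angle to two projection series
#' recorded below and above the edge, producing a difference-map series that
#' the tomography module can reconstruct into a 3D elemental distribution.
#'
#' @param below_series,above_series `projection_series` objects on the same
#'   angle grid (optical density).
#' @param energies_eV Length-2 vector `c(below, above)` in eV.
#' @param zp,geom Optics model, or `NULL` to skip magnification correction.
#' @param element Element label.
#' @return A `projection_series` of difference maps.
#' @export
difference_series <- function(below_series, above_series, energies_eV,
                              zp = NULL, geom = NULL, element = "") {
  if (!isTRUE(all.equal(below_series$angles_deg, above_series$angles_deg)))
    stop("below and above series must share the same angle grid")
  n <- n_frames(below_series)
  out <- below_series$data
  for (i in seq_len(n)) {
    pair <- two_energy_pair(
      image_frame(get_frame(below_series, i), energy_eV = energies_eV[1],
                  angle_deg = below_series$angles_deg[i]),
      image_frame(get_frame(above_series, i), energy_eV = energies_eV[2],
                  angle_deg = above_series$angles_deg[i]),
      element = element)
    out[i, , ] <- difference_map(pair, zp, geom)
  }
  projection_series(out, below_series$angles_deg,
                    pixel_size_nm = below_series$pixel_size_nm)
}
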