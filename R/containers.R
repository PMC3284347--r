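#' @title Core data containers
#' @description S3 containers used throughout the toolkit: single detector
#'   frames with their acquisition metadata, energy-resolved image stacks
#'   (the substrate of XANES imaging) and angle-resolved projection series
#'   (the substrate of tomography).
#' @name containers
#' @keywords internal
NULL

#' Construct a single image frame with acquisition metadata
#'
#' An `image_frame` couples one 2D detector image with the metadata needed by
#' the downstream pipeline: incident X-ray energy, sample-stage angle, motor
#' positions and the detector pixel size.  Frames destined for one stack must
#' share their pixel shape and pixel size.
#'
#' @param pixels Numeric matrix (rows x cols); detector counts, transmission
#'   or optical density depending on the processing stage.
#' @param energy_eV Incident X-ray energy in eV (> 0).
#' @param angle_deg Sample stage rotation angle in degrees.
#' @param motor_x_um,motor_y_um Stage motor positions in micrometres.
#' @param pixel_size_nm Detector pixel size in nanometres (> 0).
#' @param exposure_s Optional exposure time in seconds.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, energy_eV = NA_real_, angle_deg = NA_real_,
                        motor_x_um = NA_real_, motor_y_um = NA_real_,
                        pixel_size_nm = NA_real_, exposure_s = NA_real_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!is.na(energy_eV) && energy_eV <= 0) stop("energy_eV must be > 0")
  if (!is.na(pixel_size_nm) && pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  structure(list(pixels = pixels, energy_eV = energy_eV, angle_deg = angle_deg,
                 motor_x_um = motor_x_um, motor_y_um = motor_y_um,
                 pixel_size_nm = pixel_size_nm, exposure_s = exposure_s),
            class = "image_frame")
}

#' Construct an energy stack
#'
#' An `energy_stack` holds the aligned 3D cube recorded during an energy scan:
#' one image per energy, stored as a `(n_energies, H, W)` array.  After
#' reference correction and conversion to optical density it is the substrate
#' for all XANES-imaging analysis.
#'
#' @param data 3D numeric array, dimension `(n_energies, H, W)`.
#' @param energies_eV Strictly increasing numeric vector of energies (eV),
#'   one per frame.  Frames are reordered if given unsorted.
#' @param corrected Logical flag: has flat-field (reference) correction been
#'   applied?
#' @param pixel_size_nm Pixel size in nm, if known.
#' @return An object of class `energy_stack`.
#' @export
energy_stack <- function(data, energies_eV, corrected = FALSE,
                         pixel_size_nm = NA_real_) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(energies_eV))
    stop("length(energies_eV) must equal dim(data)[1]")
  if (anyDuplicated(energies_eV))
    stop("energies_eV contains duplicates")
  ord <- order(energies_eV)
  data <- data[ord, , , drop = FALSE]
  energies_eV <- energies_eV[ord]
  if (!all(is.finite(data))) stop("stack data must be finite everywhere")
  structure(list(data = data, energies_eV = as.numeric(energies_eV),
                 corrected = isTRUE(corrected), pixel_size_nm = pixel_size_nm),
            class = "energy_stack")
}

#' Construct a projection series
#'
#' A `projection_series` holds the 3D cube recorded during a tomographic scan:
#' one image per stage angle, stored as a `(n_angles, H, W)` array.
#'
#' @param data 3D numeric array, dimension `(n_angles, H, W)`.
#' @param angles_deg Strictly increasing numeric vector of stage angles
#'   (degrees) spanning at most one full turn.  Frames are reordered if given
#'   unsorted.
#' @param pixel_size_nm Pixel size in nm, if known.
#' @return An object of class `projection_series`.
#' @export
projection_series <- function(data, angles_deg, pixel_size_nm = NA_real_) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(angles_deg))
    stop("length(angles_deg) must equal dim(data)[1]")
  if (anyDuplicated(angles_deg)) stop("angles_deg contains duplicates")
  ord <- order(angles_deg)
  data <- data[ord, , , drop = FALSE]
  angles_deg <- as.numeric(angles_deg[ord])
  if (diff(range(angles_deg)) > 360)
    stop("angles_deg must lie within one 360 degree span")
  structure(list(data = data, angles_deg = angles_deg,
                 pixel_size_nm = pixel_size_nm),
            class = "projection_series")
}

#' @export
print.energy_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<energy_stack> %d energies x %d x %d px, %.1f-%.1f eV%s\n",
              d[1], d[2], d[3], min(x$energies_eV), max(x$energies_eV),
              if (x$corrected) ", reference-corrected" else ""))
  invisible(x)
}

#' @export
print.projection_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<projection_series> %d angles x %d x %d px, %.1f-%.1f deg\n",
              d[1], d[2], d[3], min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Number of frames in a stack or series
#' @param x An `energy_stack` or `projection_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$data)[1]

#' Extract one frame as a matrix
#' @param x An `energy_stack` or `projection_series`.
#' @param i Frame index (1-based).
#' @return Numeric matrix `(H, W)`.
#' @export
get_frame <- function(x, i) {
  x$data[i, , , drop = TRUE]
}
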