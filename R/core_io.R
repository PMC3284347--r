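#' @title Stack input/output and intensity pre-treatment
#' @description Reading/writing TIFF series (with CSV metadata sidecars) and
#'   self-describing HDF5 containers, flat-field (reference) correction, and
#'   conversion of transmission to optical density.
#' @name core_io
NULL

# Floors guaranteeing finite optical density (see vignette, "Numerical
# choices"): transmission below T_FLOOR is clipped; reference pixels below
# 1e-6 x median(reference) are flagged invalid.
T_FLOOR <- 1e-6
REF_FLOOR_REL <- 1e-6

.read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("file", "energy_eV", "angle_deg", "motor_x_um", "motor_y_um")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata sidecar is missing column(s): ", paste(missing, collapse = ", "))
  md
}

#' Read an image stack from a TIFF series or an HDF5 container
#'
#' For a TIFF series, `paths` lists the frame files and `metadata` is a CSV
#' sidecar (columns `file,energy_eV,angle_deg,motor_x_um,motor_y_um`, plus
#' optional `pixel_size_nm`) or an equivalent data frame; rows are matched to
#' `paths` by the `file` column (basename).  For HDF5, `paths` is a single
#' `.h5`/`.hdf5` path laid out as written by [write_stack()]: datasets
#' `/data`, `/energies_eV` or `/angles_deg`, `/motor_xy_um`,
#' `/pixel_size_nm`.
#'
#' Frames are sorted by energy (energy stacks) or by angle (projection
#' series); a shape mismatch is a hard error naming the offending file.
#'
#' @param paths Character vector of TIFF paths, or one HDF5 path.
#' @param metadata CSV path or data frame (TIFF series only).
#' @param kind `"energy"` or `"angle"`; which axis orders the stack.
#' @return An [energy_stack()] (`kind = "energy"`) or a
#'   [projection_series()] (`kind = "angle"`).
#' @export
read_stack <- function(paths, metadata = NULL, kind = c("energy", "angle")) {
  kind <- match.arg(kind)
  if (length(paths) == 1 && grepl("\\.(h5|hdf5)$", paths, ignore.case = TRUE))
    return(.read_stack_h5(paths, kind))
  if (is.character(metadata)) metadata <- .read_metadata_csv(metadata)
  if (is.null(metadata)) stop("a metadata sidecar is required for TIFF series")
  required <- c("file", "energy_eV", "angle_deg", "motor_x_um", "motor_y_um")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(metadata) != length(paths))
    stop("metadata has ", nrow(metadata), " rows but ", length(paths),
         " frame files were given")
  md <- metadata[match(basename(paths), basename(metadata$file)), ]
  if (anyNA(md$energy_eV) && kind == "energy")
    stop("metadata rows could not be matched to all frame files")
  frames <- lapply(paths, read_tiff)
  shp <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), shp))
      stop("frame shape mismatch: ", paths[i], " is ",
           paste(dim(frames[[i]]), collapse = "x"), ", expected ",
           paste(shp, collapse = "x"))
  }
  data <- array(0, dim = c(length(frames), shp[1], shp[2]))
  for (i in seq_along(frames)) data[i, , ] <- frames[[i]]
  ps <- if ("pixel_size_nm" %in% names(md)) md$pixel_size_nm[1] else NA_real_
  out <- if (kind == "energy") {
    energy_stack(data, md$energy_eV, corrected = FALSE, pixel_size_nm = ps)
  } else {
    projection_series(data, md$angle_deg, pixel_size_nm = ps)
  }
  out$motor_x_um <- md$motor_x_um[order(if (kind == "energy") md$energy_eV else md$angle_deg)]
  out$motor_y_um <- md$motor_y_um[order(if (kind == "energy") md$energy_eV else md$angle_deg)]
  out
}

.read_stack_h5 <- function(path, kind) {
  data <- rhdf5::h5read(path, "data")
  nm <- vapply(rhdf5::h5ls(path)$name, identity, character(1))
  ps <- if ("pixel_size_nm" %in% nm) as.numeric(rhdf5::h5read(path, "pixel_size_nm")) else NA_real_
  if (kind == "energy") {
    if (!("energies_eV" %in% nm)) stop("HDF5 file has no /energies_eV dataset")
    energy_stack(data, as.numeric(rhdf5::h5read(path, "energies_eV")),
                 corrected = FALSE, pixel_size_nm = ps)
  } else {
    if (!("angles_deg" %in% nm)) stop("HDF5 file has no /angles_deg dataset")
    projection_series(data, as.numeric(rhdf5::h5read(path, "angles_deg")),
                      pixel_size_nm = ps)
  }
}

#' Write a stack to disk
#'
#' `format = "h5"` writes one self-describing HDF5 container (`/data`,
#' `/energies_eV` or `/angles_deg`, `/motor_xy_um`, `/pixel_size_nm`).
#' `format = "tiff"` writes one float32 TIFF per frame into directory `path`
#' plus a CSV metadata sidecar `metadata.csv`, bit-exact and diffable.
#'
#' @param x An `energy_stack` or `projection_series`.
#' @param path Output `.h5` file, or directory for a TIFF series.
#' @param format `"h5"` or `"tiff"`.
#' @param type TIFF sample type, see [write_tiff()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, format = c("h5", "tiff"),
                        type = c("float32", "uint16")) {
  format <- match.arg(format)
  axis_name <- if (inherits(x, "energy_stack")) "energies_eV" else "angles_deg"
  axis <- if (inherits(x, "energy_stack")) x$energies_eV else x$angles_deg
  if (format == "h5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(x$data, path, "data")
    rhdf5::h5write(axis, path, axis_name)
    mx <- if (is.null(x$motor_x_um)) rep(NA_real_, n_frames(x)) else x$motor_x_um
    my <- if (is.null(x$motor_y_um)) rep(NA_real_, n_frames(x)) else x$motor_y_um
    rhdf5::h5write(cbind(mx, my), path, "motor_xy_um")
    rhdf5::h5write(x$pixel_size_nm, path, "pixel_size_nm")
    rhdf5::h5closeAll()
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- sprintf("frame_%04d.tif", seq_len(n_frames(x)))
    for (i in seq_len(n_frames(x)))
      write_tiff(get_frame(x, i), file.path(path, files[i]), type = match.arg(type))
    md <- data.frame(
      file = files,
      energy_eV = if (inherits(x, "energy_stack")) axis else NA_real_,
      angle_deg = if (inherits(x, "projection_series")) axis else NA_real_,
      motor_x_um = if (is.null(x$motor_x_um)) 0 else x$motor_x_um,
      motor_y_um = if (is.null(x$motor_y_um)) 0 else x$motor_y_um,
      pixel_size_nm = x$pixel_size_nm)
    utils::write.csv(md, file.path(path, "metadata.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Flat-field (reference) correction
#'
#' Divides a sample image by a reference image recorded without the sample at
#' the same energy, yielding transmission.  Reference pixels at or below a
#' floor of `1e-6 * median(reference)` cannot be trusted; they are clipped for
#' the division and flagged in the `"invalid"` attribute of the result.
#'
#' @param sample 2D numeric matrix of detector counts.
#' @param reference 2D numeric matrix, same shape.
#' @return Transmission matrix with logical attribute `"invalid"`.
#' @export
reference_correct <- function(sample, reference) {
  sample <- as.matrix(sample); reference <- as.matrix(reference)
  if (!identical(dim(sample), dim(reference)))
    stop("sample and reference must have identical shape")
  if (all(reference <= 0)) stop("reference image is entirely non-positive")
  floor_val <- REF_FLOOR_REL * stats::median(reference)
  invalid <- reference <= floor_val
  trans <- sample / pmax(reference, floor_val)
  attr(trans, "invalid") <- invalid
  trans
}

#' Convert transmission to optical density
#'
#' Beer-Lambert conversion `OD = -ln(T)`.  Transmission is additive in
#' nothing, but OD is additive in absorber thickness, which is what makes the
#' XANES edge jump proportional to areal concentration; the whole analysis
#' pipeline therefore works in OD.  Values at or below the floor `1e-6` are
#' clipped so the result is finite everywhere; the number of clipped pixels
#' is reported in the `"n_clipped"` attribute (and as a message when
#' nonzero).
#'
#' @param transmission Numeric array (any shape) of transmission values,
#'   nominally in `(0, 1 + eps]`.
#' @return Array of the same shape: optical density, finite everywhere.
#' @export
to_optical_density <- function(transmission) {
  n_clipped <- sum(transmission <= T_FLOOR)
  od <- -log(pmax(transmission, T_FLOOR))
  if (n_clipped > 0)
    message(n_clipped, " pixel(s) at or below the transmission floor were clipped")
  attr(od, "n_clipped") <- n_clipped
  od
}

#' Reference-correct and OD-convert a whole stack
#'
#' Convenience driver: applies [reference_correct()] with per-energy
#' references (or one shared reference) and [to_optical_density()] to every
#' frame.
#'
#' @param stack An `energy_stack` (or `projection_series`) of raw counts.
#' @param references One matrix shared by all frames, or a list with one
#'   matrix per frame.
#' @return A stack of the same class in optical density, `corrected = TRUE`.
#' @export
correct_stack <- function(stack, references) {
  one <- is.matrix(references)
  out <- stack$data
  for (i in seq_len(n_frames(stack))) {
    ref <- if (one) references else references[[i]]
    trans <- reference_correct(get_frame(stack, i), ref)
    out[i, , ] <- suppressMessages(to_optical_density(trans))
  }
  stack$data <- out
  stack$corrected <- TRUE
  stack
}
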