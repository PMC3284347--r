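#' @title Mosaic stitching
#' @description Composes overlapping image tiles (multiple fields of view)
#'   into one large image.  Encoded stage motor positions seed the layout;
#'   residual motor errors are measured by phase correlation over the
#'   overlap strips of 4-neighbour tile pairs and reconciled by a global
#'   least-squares placement; tiles are blended with a feathered weighted
#'   average over the overlap, which suppresses the poorer signal-to-noise
#'   ratio of tile corners.
#' @name mosaic
NULL

#' Seed tile offsets from encoded motor positions
#'
#' Converts each tile's stage position to a pixel offset relative to the
#' minimum position: `offset_px = (motor_um - min(motor_um)) * 1000 /
#' pixel_size_nm` (motor y maps to rows, motor x to columns).  Fractional
#' offsets are retained for blending; rounded values seed overlap cropping.
#'
#' @param tiles List of [image_frame()]s with motor and pixel-size metadata.
#' @return `n x 2` matrix of fractional `(row, col)` offsets.
#' @export
nominal_positions <- function(tiles) {
  mx <- vapply(tiles, function(t) t$motor_x_um, numeric(1))
  my <- vapply(tiles, function(t) t$motor_y_um, numeric(1))
  ps <- vapply(tiles, function(t) t$pixel_size_nm, numeric(1))
  if (anyNA(c(mx, my, ps)))
    stop("motor positions and pixel size are required for mosaic seeding; ",
         "no fallback grid guessing")
  off <- cbind(row = (my - min(my)) * 1000 / ps,
               col = (mx - min(mx)) * 1000 / ps)
  if (length(tiles) > 1 && anyDuplicated(round(off)) > 0)
    warning("tiles with identical motor positions detected (duplicates?)")
  off
}

#' Assemble a mosaic layout
#'
#' @param tiles List of [image_frame()]s (all the same pixel shape).
#' @param overlap_frac Design overlap fraction in `[0, 0.9]`.
#' @return A `mosaic_layout`: tiles, fractional `nominal_px`, `refined_px`
#'   (initially `NULL`), `overlap_frac` and `links` (filled by
#'   [refine_offsets()]).
#' @export
mosaic_layout <- function(tiles, overlap_frac = 0.2) {
  stopifnot(overlap_frac >= 0, overlap_frac <= 0.9)
  shp <- dim(tiles[[1]]$pixels)
  for (t in tiles) stopifnot(identical(dim(t$pixels), shp))
  structure(list(tiles = tiles, nominal_px = nominal_positions(tiles),
                 refined_px = NULL, overlap_frac = overlap_frac,
                 links = NULL),
            class = "mosaic_layout")
}

# Overlap box of two tiles (rounded offsets, canvas coords); NULL if none.
.overlap_box <- function(oi, oj, h, w) {
  r0 <- max(oi[1], oj[1]); r1 <- min(oi[1] + h, oj[1] + h)
  c0 <- max(oi[2], oj[2]); c1 <- min(oi[2] + w, oj[2] + w)
  if (r1 - r0 < 1 || c1 - c0 < 1) return(NULL)
  c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
}

#' Refine tile offsets by phase correlation over overlap strips
#'
#' For every 4-neighbour pair (tile pairs sharing a substantial overlap
#' strip) the nominal overlap regions are cropped and their residual
#' displacement measured by [phase_correlate()].  All tile offsets are then
#' solved jointly by least squares over the pairwise link constraints with
#' tile 1 anchored at its nominal position.  Links with a correlation peak
#' below `q_min` (e.g. featureless tiles) are dropped from the solve; tiles
#' left disconnected keep their nominal offsets, with a warning.
#'
#' @param layout A [mosaic_layout()].
#' @param q_min Minimum link peak quality (default 0.05).
#' @param min_overlap Minimum usable overlap in pixels (default 16); thinner
#'   overlaps are skipped with a warning.
#' @return The layout with `refined_px` and `links` filled in.
#' @export
refine_offsets <- function(layout, q_min = 0.05, min_overlap = 16) {
  tiles <- layout$tiles
  n <- length(tiles)
  h <- nrow(tiles[[1]]$pixels); w <- ncol(tiles[[1]]$pixels)
  nom <- layout$nominal_px
  nomr <- round(nom)
  links <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    box <- .overlap_box(nomr[i, ], nomr[j, ], h, w)
    if (is.null(box)) next
    oh <- box["r1"] - box["r0"]; ow <- box["c1"] - box["c0"]
    strip_like <- (oh >= 0.6 * h && ow < 0.6 * w) ||
                  (ow >= 0.6 * w && oh < 0.6 * h)
    if (!strip_like) next                       # not a 4-neighbour pair
    if (min(oh, ow) < min_overlap) {
      warning("overlap between tiles ", i, " and ", j, " is below ",
              min_overlap, " px; link skipped")
      next
    }
    crop <- function(k) {
      r <- (box["r0"] - nomr[k, 1] + 1):(box["r1"] - nomr[k, 1])
      c <- (box["c0"] - nomr[k, 2] + 1):(box["c1"] - nomr[k, 2])
      tiles[[k]]$pixels[r, c, drop = FALSE]
    }
    s <- tryCatch(phase_correlate(crop(i), crop(j)),
                  error = function(e) NULL)
    if (is.null(s)) next
    links[[length(links) + 1]] <-
      list(i = i, j = j, dy = s$dy, dx = s$dx,
           peak_quality = s$peak_quality, used = s$peak_quality >= q_min)
  }
  refined <- nom
  used <- Filter(function(l) l$used, links)
  if (length(used)) {
    # connected components over used links, tile 1's component anchored
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (l in used) {
        m <- min(comp[l$i], comp[l$j])
        if (comp[l$i] != m || comp[l$j] != m) {
          comp[comp == comp[l$i] | comp == comp[l$j]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(comp)) > 1)
      warning("mosaic link graph is disconnected; each component is ",
              "anchored at its own nominal position")
    # per-axis least squares: t_j - t_i = (nom_j - nom_i) - shift_ij,
    # plus one anchor equation per component
    anchors <- vapply(unique(comp), function(cc) min(which(comp == cc)),
                      integer(1))
    nr <- length(used) + length(anchors)
    A <- matrix(0, nr, n)
    b_row <- numeric(nr); b_col <- numeric(nr)
    for (k in seq_along(used)) {
      l <- used[[k]]
      A[k, l$i] <- -1; A[k, l$j] <- 1
      b_row[k] <- (nom[l$j, 1] - nom[l$i, 1]) - l$dy
      b_col[k] <- (nom[l$j, 2] - nom[l$i, 2]) - l$dx
    }
    for (k in seq_along(anchors)) {
      A[length(used) + k, anchors[k]] <- 1
      b_row[length(used) + k] <- nom[anchors[k], 1]
      b_col[length(used) + k] <- nom[anchors[k], 2]
    }
    refined <- cbind(row = stats::lsfit(A, b_row, intercept = FALSE)$coefficients,
                     col = stats::lsfit(A, b_col, intercept = FALSE)$coefficients)
    rownames(refined) <- NULL
  }
  layout$refined_px <- refined
  layout$links <- links
  layout
}

#' Blend a mosaic layout into one stitched image
#'
#' Each tile contributes with a separable feathering weight: a linear ramp
#' from ~0 at the tile border to 1 at the feather width (the measured
#' overlap extent, floor 8 px), so tile corners -- which have the poorest
#' signal-to-noise ratio -- are down-weighted and seams disappear.  The
#' output pixel is `sum(w_i * tile_i) / sum(w_i)`; the convex combination
#' guarantees no over/undershoot.  Fractional offsets are honoured by
#' bicubic resampling before placement.
#'
#' @param layout A [mosaic_layout()], ideally after [refine_offsets()].
#' @param use `"refined"` (fall back to nominal if absent) or `"nominal"`.
#' @param fill Value for canvas pixels no tile covers (default `NA`).
#' @return List: `image` (stitched canvas), `weight` (summed weight map) and
#'   `mask` (logical, `TRUE` where covered).
#' @export
blend <- function(layout, use = c("refined", "nominal"), fill = NA_real_) {
  use <- match.arg(use)
  off <- if (use == "refined" && !is.null(layout$refined_px))
    layout$refined_px else layout$nominal_px
  tiles <- layout$tiles
  n <- length(tiles)
  h <- nrow(tiles[[1]]$pixels); w <- ncol(tiles[[1]]$pixels)
  oint <- round(off)
  frac <- off - oint
  oint[, 1] <- oint[, 1] - min(oint[, 1])
  oint[, 2] <- oint[, 2] - min(oint[, 2])
  H <- max(oint[, 1]) + h; W <- max(oint[, 2]) + w
  # feather widths from measured overlap extents (floor 8 px)
  fw_r <- fw_c <- 8
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    box <- .overlap_box(oint[i, ], oint[j, ], h, w)
    if (is.null(box)) next
    oh <- box["r1"] - box["r0"]; ow <- box["c1"] - box["c0"]
    if (oh >= 0.6 * h) fw_c <- max(fw_c, ow)    # side-by-side pair
    if (ow >= 0.6 * w) fw_r <- max(fw_r, oh)    # stacked pair
  }
  wr <- pmin((seq_len(h) - 0.5) / fw_r, (h - seq_len(h) + 0.5) / fw_r, 1)
  wc <- pmin((seq_len(w) - 0.5) / fw_c, (w - seq_len(w) + 0.5) / fw_c, 1)
  wgt <- outer(wr, wc)
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  for (k in seq_len(n)) {
    px <- tiles[[k]]$pixels
    if (max(abs(frac[k, ])) > 1e-9)
      px <- translate_image(px, -frac[k, 1], -frac[k, 2])
    rr <- oint[k, 1] + seq_len(h); cc <- oint[k, 2] + seq_len(w)
    num[rr, cc] <- num[rr, cc] + wgt * px
    den[rr, cc] <- den[rr, cc] + wgt
  }
  img <- matrix(fill, H, W)
  ok <- den > 0
  img[ok] <- num[ok] / den[ok]
  list(image = img, weight = den, mask = ok)
}

#' One-call mosaic stitching
#'
#' Seeds from motor positions, refines by phase correlation and blends.
#'
#' @inheritParams mosaic_layout
#' @inheritParams refine_offsets
#' @return As [blend()], plus the refined `layout`.
#' @export
stitch_mosaic <- function(tiles, overlap_frac = 0.2, q_min = 0.05,
                          min_overlap = 16) {
  layout <- refine_offsets(mosaic_layout(tiles, overlap_frac),
                           q_min = q_min, min_overlap = min_overlap)
  out <- blend(layout)
  out$layout <- layout
  out
}
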