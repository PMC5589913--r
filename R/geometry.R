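#' Imaging metadata
#'
#' Physical calibration of a time-lapse movie: the pixel size in micrometers
#' per pixel, the frame interval in seconds, and which image axis carries the
#' embryo's anterior-posterior (AP) axis. All geometric measurements in the
#' package are reported in micrometers using this calibration; pixel-unit
#' originals are retained alongside.
#'
#' @param pixel_size micrometers per pixel (> 0). Default 0.164, the spinning
#'   disk calibration typical of the intended acquisitions.
#' @param frame_interval seconds per frame (> 0). Default 1.
#' @param ap_axis which image axis is the AP axis: `"horizontal"` (columns;
#'   the default, anterior to the left) or `"vertical"`.
#' @return an object of class `imaging_metadata`.
#' @export
imaging_metadata <- function(pixel_size = 0.164, frame_interval = 1,
                             ap_axis = c("horizontal", "vertical")) {
  ap_axis <- match.arg(ap_axis)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop_invalid("pixel_size must be a positive finite number", "invalid_input")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop_invalid("frame_interval must be a positive finite number", "invalid_input")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 ap_axis = ap_axis),
            class = "imaging_metadata")
}

#' @export
print.imaging_metadata <- function(x, ...) {
  cat(sprintf("imaging_metadata: %.4g um/px, %.4g s/frame, AP axis %s\n",
              x$pixel_size, x$frame_interval, x$ap_axis))
  invisible(x)
}

#' Interface length from its two vertices
#'
#' The length of a cell-cell interface is the Euclidean distance between its
#' two tricellular vertices, converted to micrometers. Contour arc length is
#' deliberately not used; the chord between vertices is the length that enters
#' all trajectory statistics.
#'
#' @param v1,v2 numeric length-2 vertex positions `(row, col)` in pixels.
#' @param meta an [imaging_metadata].
#' @return length in micrometers (>= 0).
#' @examples
#' m <- imaging_metadata(pixel_size = 1)
#' interface_length(c(0, 0), c(3, 4), m)  # 5
#' @export
interface_length <- function(v1, v2, meta = imaging_metadata()) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != 2L || length(v2) != 2L || !all(is.finite(c(v1, v2))))
    stop_invalid("vertex positions must be finite (row, col) pairs", "invalid_input")
  sqrt(sum((v1 - v2)^2)) * meta$pixel_size
}

#' Interface orientation angle
#'
#' Orientation of the vertex-vertex chord measured from the AP (horizontal)
#' image axis, counter-clockwise, folded to `[0, 180)` degrees. A vertical
#' interface (between AP neighbor cells) reports 90 degrees; with the
#' `[75, 105]` band this makes "within 15 degrees of the DV axis" the AP
#' interface class.
#'
#' @inheritParams interface_length
#' @return angle in degrees in `[0, 180)`.
#' @export
interface_angle <- function(v1, v2, meta = imaging_metadata()) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (!all(is.finite(c(v1, v2))))
    stop_invalid("vertex positions must be finite", "invalid_input")
  d <- v2 - v1
  if (all(d == 0))
    stop_invalid("zero-length interface has no orientation", "degenerate_interface")
  # image rows grow downward; fold to [0, 180) so orientation is symmetric
  ang <- atan2(d[1], d[2]) * 180 / pi
  ang <- ang %% 180
  if (meta$ap_axis == "vertical") ang <- (ang + 90) %% 180
  if (ang >= 180) ang <- 0
  ang
}

#' Construct a tissue frame
#'
#' A `tissue_frame` is the skeletonized representation of one segmented movie
#' frame: an integer label image (0 = background), plus tables of cells,
#' vertices and interfaces and the imaging calibration.
#'
#' @param frame_index 1-based frame number.
#' @param label_image integer matrix of cell labels, 0 for background.
#' @param cells data.frame with columns `cell_id`, `centroid_r`, `centroid_c`,
#'   `area_px`, `area_um2`, `perimeter_um`, `neighbors` (list column of
#'   integer vectors), `touches_border`.
#' @param vertices data.frame with `vertex_id`, `r`, `c`, `interfaces`
#'   (list column).
#' @param interfaces data.frame with `interface_id`, `cell_a`, `cell_b`,
#'   `vertex_1`, `vertex_2`, `length_px`, `length_um`, `angle_deg`, `class`,
#'   `contour` (list column of n x 2 pixel matrices).
#' @param metadata an [imaging_metadata].
#' @return object of class `tissue_frame`.
#' @export
tissue_frame <- function(frame_index, label_image, cells, vertices,
                         interfaces, metadata = imaging_metadata()) {
  structure(list(frame_index = frame_index, label_image = label_image,
                 cells = cells, vertices = vertices,
                 interfaces = interfaces, metadata = metadata),
            class = "tissue_frame")
}

#' @export
print.tissue_frame <- function(x, ...) {
  cat(sprintf("tissue_frame %d: %d cells, %d interfaces, %d vertices (%dx%d px)\n",
              x$frame_index, nrow(x$cells), nrow(x$interfaces),
              nrow(x$vertices), nrow(x$label_image), ncol(x$label_image)))
  invisible(x)
}

#' Validate the internal consistency of a tissue frame
#'
#' Report-only checker for the tissue-frame invariants: positive areas,
#' symmetric cell adjacency, border flags consistent with the label image,
#' stored interface lengths equal to the vertex-vertex distance, and interface
#' cell pairs that are mutual neighbors.
#'
#' @param frame a [tissue_frame].
#' @return character vector of violation messages (empty when consistent).
#' @export
validate_frame <- function(frame) {
  v <- character(0)
  cells <- frame$cells
  if (nrow(cells)) {
    if (any(cells$area_px <= 0))
      v <- c(v, "cell with non-positive area")
    nb <- stats::setNames(cells$neighbors, as.character(cells$cell_id))
    for (i in seq_len(nrow(cells))) {
      for (j in nb[[i]]) {
        other <- nb[[as.character(j)]]
        if (is.null(other) || !(cells$cell_id[i] %in% other))
          v <- c(v, sprintf("asymmetric adjacency: %d -> %d", cells$cell_id[i], j))
      }
    }
    lab <- frame$label_image
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    for (i in seq_len(nrow(cells))) {
      touches <- cells$cell_id[i] %in% border_labels ||
        touches_background(lab, cells$cell_id[i])
      if (isTRUE(cells$touches_border[i]) != touches)
        v <- c(v, sprintf("border flag wrong for cell %d", cells$cell_id[i]))
    }
  }
  ints <- frame$interfaces
  if (nrow(ints)) {
    vert <- frame$vertices
    for (i in seq_len(nrow(ints))) {
      i1 <- match(ints$vertex_1[i], vert$vertex_id)
      i2 <- match(ints$vertex_2[i], vert$vertex_id)
      if (is.na(i1) || is.na(i2)) next
      d <- interface_length(c(vert$r[i1], vert$c[i1]), c(vert$r[i2], vert$c[i2]),
                            frame$metadata)
      if (abs(d - ints$length_um[i]) > 1e-6 * max(1, d))
        v <- c(v, sprintf("interface %s length %.4f != vertex distance %.4f",
                          ints$interface_id[i], ints$length_um[i], d))
      a <- match(ints$cell_a[i], cells$cell_id)
      b <- match(ints$cell_b[i], cells$cell_id)
      if (!is.na(a) && !is.na(b) &&
          !(ints$cell_b[i] %in% cells$neighbors[[a]] &&
            ints$cell_a[i] %in% cells$neighbors[[b]]))
        v <- c(v, sprintf("interface %s cells are not mutual neighbors",
                          ints$interface_id[i]))
    }
  }
  v
}

# TRUE if any pixel of `label` is 4-adjacent to background (label 0).
touches_background <- function(lab, label) {
  m <- lab == label
  if (!any(m)) return(FALSE)
  nr <- nrow(lab); nc <- ncol(lab)
  sh <- function(off_r, off_c) {
    out <- matrix(NA_integer_, nr, nc)
    rs <- seq_len(nr) + off_r; cs <- seq_len(nc) + off_c
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- lab[rs[ok_r], cs[ok_c]]
    out
  }
  any(m & (sh(1, 0) == 0 | sh(-1, 0) == 0 | sh(0, 1) == 0 | sh(0, -1) == 0),
      na.rm = TRUE)
}
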