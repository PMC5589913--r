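#' Assign a compartment detection to an interface or the apical surface
#'
#' A compartment is uniquely associated with an interface iff all three
#' geometric rules hold: (i) its centroid is on or within `dist_cutoff`
#' pixels of the interface contour; (ii) it is strictly closer to that
#' interface than to any other (ties within 1e-9 px yield APICAL, since the
#' association must be unique); (iii) it is at least min(1 px, 0.1 x
#' interface length) away from the interface's closest vertex. Otherwise the
#' compartment is apical.
#'
#' @param centroid numeric `(row, col)` in pixels.
#' @param frame a [tissue_frame].
#' @param dist_cutoff rule (i) cutoff in pixels (default 10 px = 1.66 um).
#' @param .cache internal: precomputed [frame_contour_cache] for batch use.
#' @return list: `interface_id` (character or `"APICAL"`), `distance_px`
#'   (to the winning interface contour, NA if apical), `side` (which cell of
#'   the pair contains/is nearest the centroid, NA if apical).
#' @export
associate <- function(centroid, frame, dist_cutoff = 10, .cache = NULL) {
  lab <- frame$label_image
  r0 <- round(centroid[1]); c0 <- round(centroid[2])
  if (r0 < 1 || c0 < 1 || r0 > nrow(lab) || c0 > ncol(lab) ||
      lab[r0, c0] == 0L)
    stop_invalid("detection centroid outside the segmented tissue", "out_of_tissue")
  ints <- frame$interfaces
  if (!nrow(ints)) return(list(interface_id = "APICAL", distance_px = NA_real_,
                               side = NA_integer_))
  geo <- if (is.null(.cache)) frame_contour_cache(frame) else .cache
  d2all <- (geo$px_r - centroid[1])^2 + (geo$px_c - centroid[2])^2
  d <- rep(Inf, nrow(ints))
  mins <- tapply(d2all, geo$px_int, min)
  d[as.integer(names(mins))] <- sqrt(mins)
  o <- order(d)
  best <- o[1]
  if (d[best] > dist_cutoff)
    return(list(interface_id = "APICAL", distance_px = NA_real_, side = NA_integer_))
  if (nrow(ints) > 1 && d[o[2]] - d[best] <= 1e-9)   # tie: not unique
    return(list(interface_id = "APICAL", distance_px = NA_real_, side = NA_integer_))
  # rule (iii): clearance from the interface's closest vertex
  vids <- c(ints$vertex_1[best], ints$vertex_2[best])
  vids <- vids[!is.na(vids)]
  if (length(vids)) {
    vv <- frame$vertices[match(vids, frame$vertices$vertex_id), ]
    dv <- min(sqrt((vv$r - centroid[1])^2 + (vv$c - centroid[2])^2))
    if (dv < min(1, 0.1 * ints$length_px[best]))
      return(list(interface_id = "APICAL", distance_px = NA_real_, side = NA_integer_))
  }
  side <- lab[r0, c0]
  if (!(side %in% c(ints$cell_a[best], ints$cell_b[best]))) {
    # centroid sits on a third cell: take the nearer of the pair's centroids
    cc <- frame$cells[match(c(ints$cell_a[best], ints$cell_b[best]),
                            frame$cells$cell_id), ]
    dcc <- (cc$centroid_r - centroid[1])^2 + (cc$centroid_c - centroid[2])^2
    side <- cc$cell_id[which.min(dcc)]
  }
  list(interface_id = ints$interface_id[best], distance_px = d[best],
       side = as.integer(side))
}

#' Track-level compartment-interface association
#'
#' Applies [associate] per detection and assigns each track by majority vote
#' over its frames (ties to the interface of the earliest associated frame).
#'
#' @param tracks a `particle_tracks` object.
#' @param frames list of [tissue_frame] (one per movie frame, persistent ids).
#' @param dist_cutoff see [associate].
#' @return data.frame of class association records: `track_id`,
#'   `interface_id` (or "APICAL"), `side`, `t_start`, `t_end`,
#'   `lifetime_frames`, `angle_deg` (time-mean interface angle over the
#'   association, NA if apical).
#' @export
associate_tracks <- function(tracks, frames, dist_cutoff = 10) {
  det <- tracks$detections
  per_det <- vector("list", nrow(det))
  for (fr in unique(det$frame)) {
    f <- frames[[fr]]
    cache <- if (nrow(f$interfaces)) frame_contour_cache(f) else NULL
    for (i in which(det$frame == fr)) {
      per_det[[i]] <- tryCatch(
        associate(c(det$r[i], det$c[i]), f, dist_cutoff, .cache = cache),
        epiratchet_error = function(e)
          list(interface_id = NA_character_,
               distance_px = NA_real_, side = NA_integer_))
    }
  }
  det$assoc <- vapply(per_det, function(x) x$interface_id, character(1))
  det$side <- vapply(per_det, function(x)
    if (is.null(x$side) || is.na(x$side)) NA_integer_ else x$side, integer(1))
  out <- lapply(sort(unique(det$track_id)), function(id) {
    rows <- det[det$track_id == id & !is.na(det$assoc), , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    tab <- table(rows$assoc)
    winners <- names(tab)[tab == max(tab)]
    win <- if (length(winners) == 1L) winners else
      rows$assoc[rows$assoc %in% winners][which.min(rows$frame[rows$assoc %in% winners])]
    ts <- min(rows$frame); te <- max(rows$frame)
    side <- if (win == "APICAL") NA_integer_ else {
      sr <- rows$side[rows$assoc == win]
      sr <- sr[!is.na(sr)]
      if (length(sr)) as.integer(names(which.max(table(sr)))) else NA_integer_
    }
    ang <- if (win == "APICAL") NA_real_ else {
      a <- vapply(rows$frame[rows$assoc == win], function(t) {
        ints <- frames[[t]]$interfaces
        ints$angle_deg[match(win, ints$interface_id)]
      }, numeric(1))
      mean_angle_deg(a[!is.na(a)])
    }
    data.frame(track_id = id, interface_id = win, side = side,
               t_start = ts, t_end = te, lifetime_frames = te - ts + 1L,
               angle_deg = ang)
  })
  do.call(rbind, out)
}

# flat vectors of all contour pixels with their interface row index
frame_contour_cache <- function(frame) {
  n_px <- vapply(frame$interfaces$contour, nrow, integer(1))
  px <- do.call(rbind, frame$interfaces$contour)
  list(px_r = px[, 1], px_c = px[, 2],
       px_int = rep(seq_along(n_px), n_px))
}
mean_angle_deg <- function(a) {
  if (!length(a)) return(NA_real_)
  th <- a * pi / 90           # double the angle
  m <- atan2(mean(sin(th)), mean(cos(th))) * 90 / pi
  m %% 180
}

#' Classify interfaces as AP or transverse by initial orientation
#'
#' The mean orientation over the first `window_s` seconds of the movie
#' decides the class: interfaces within `tol` degrees of the DV axis
#' (i.e., angle in [90 - tol, 90 + tol] under this package's convention)
#' are AP interfaces; the rest are transverse. Interfaces absent from the
#' window stay unclassified.
#'
#' @param tracked a [tracked_tissue].
#' @param window_s initial window in seconds (default 90).
#' @param tol tolerance in degrees (default 15).
#' @return data.frame `interface_id`, `initial_angle_deg`, `class`.
#' @export
classify_interfaces <- function(tracked, window_s = 90, tol = 15) {
  dt <- tracked$metadata$frame_interval
  nwin <- min(nrow(tracked$interface_angles), max(1L, round(window_s / dt)))
  ids <- colnames(tracked$interface_angles)
  ang <- vapply(seq_along(ids), function(j) {
    a <- tracked$interface_angles[seq_len(nwin), j]
    mean_angle_deg(a[!is.na(a)])
  }, numeric(1))
  cls <- ifelse(is.na(ang), "unclassified",
                ifelse(abs(ang - 90) <= tol, "AP", "transverse"))
  data.frame(interface_id = ids, initial_angle_deg = ang, class = cls,
             stringsAsFactors = FALSE)
}

#' Compartment density versus interface orientation
#'
#' Density(t) = N_compartments(t) / N_interfaces(t) per orientation bin:
#' the number of compartments associated with interfaces whose angle falls
#' in the bin, divided by the number of interfaces in the bin, per frame;
#' the time-averaged profile and the polarity summary fractions (share of
#' interface-associated compartments within 30 degrees of the vertical and
#' of the horizontal axis) are also returned. Bins with no interfaces give
#' NA, not zero.
#'
#' @param frames list of [tissue_frame] with persistent interface ids.
#' @param associations data.frame from [associate_tracks].
#' @param bin_width orientation bin width in degrees (default 15).
#' @return list: `per_frame` (frame x bin density matrix), `profile`
#'   data.frame (`bin_lo`, `bin_hi`, `density`), `fraction_vertical`,
#'   `fraction_horizontal` (of interface-associated compartments),
#'   `n_compartments`.
#' @export
density_profile <- function(frames, associations, bin_width = 15) {
  breaks <- seq(0, 180, by = bin_width)
  nb <- length(breaks) - 1L
  nfr <- length(frames)
  dens <- matrix(NA_real_, nfr, nb)
  assoc <- associations[associations$interface_id != "APICAL", , drop = FALSE]
  for (t in seq_len(nfr)) {
    ints <- frames[[t]]$interfaces
    if (!nrow(ints)) next
    ibin <- findInterval(ints$angle_deg %% 180, breaks, rightmost.closed = TRUE)
    n_int <- tabulate(ibin, nb)
    live <- assoc[assoc$t_start <= t & assoc$t_end >= t, , drop = FALSE]
    abin <- ibin[match(live$interface_id, ints$interface_id)]
    n_spot <- tabulate(abin[!is.na(abin)], nb)
    dens[t, ] <- ifelse(n_int > 0, n_spot / n_int, NA_real_)
  }
  profile <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                        density = colMeans(dens, na.rm = TRUE))
  ang <- assoc$angle_deg
  frac_v <- if (nrow(assoc)) mean(abs(ang - 90) <= 30, na.rm = TRUE) else NA_real_
  frac_h <- if (nrow(assoc)) mean(pmin(ang, 180 - ang) <= 30, na.rm = TRUE) else NA_real_
  list(per_frame = dens, profile = profile,
       fraction_vertical = frac_v, fraction_horizontal = frac_h,
       n_compartments = nrow(associations))
}

#' Pairing and multiplicity of compartments at single interfaces
#'
#' For each interface-associated compartment event: `paired` iff a
#' compartment exists on the opposite side of the same interface with a
#' temporally overlapping span (>= 1 frame); `single` vs `multiple` by the
#' count of concurrent compartments on the same interface (either side).
#' Events lacking a side assignment are excluded.
#'
#' @param associations data.frame from [associate_tracks].
#' @return list: `events` (per-event flags), `fraction_paired`,
#'   `fraction_unpaired_strict` (no opposite-side compartment at any point
#'   during the event's lifetime), `fraction_multiple`, `n_events`.
#' @export
pairing_analysis <- function(associations) {
  ev <- associations[associations$interface_id != "APICAL", , drop = FALSE]
  dropped <- sum(is.na(ev$side))
  if (dropped) message(dropped, " events without side assignment excluded")
  ev <- ev[!is.na(ev$side), , drop = FALSE]
  n <- nrow(ev)
  if (!n) return(list(events = ev, fraction_paired = NA_real_,
                      fraction_unpaired_strict = NA_real_,
                      fraction_multiple = NA_real_, n_events = 0L))
  paired <- multiple <- logical(n)
  for (i in seq_len(n)) {
    same_int <- ev$interface_id == ev$interface_id[i] & ev$track_id != ev$track_id[i]
    overlap <- same_int & ev$t_start <= ev$t_end[i] & ev$t_end >= ev$t_start[i]
    paired[i] <- any(overlap & ev$side != ev$side[i])
    multiple[i] <- any(overlap)
  }
  ev$paired <- paired
  ev$multiple <- multiple
  list(events = ev,
       fraction_paired = mean(paired),
       fraction_unpaired_strict = mean(!paired),
       fraction_multiple = mean(multiple),
       n_events = n)
}

#' Fixed-image colocalization by grid-wise punctum overlap
#'
#' Binary puncta masks from two channels are compared: A-puncta with pixel
#' area in `size_range` are assigned to 5 x 5 um grid cells by centroid; an
#' A-punctum is colocalized iff its pixel overlap with any B-punctum exceeds
#' `min_overlap_px` pixels. The result is the weighted (by puncta count)
#' average percentage over grid cells.
#'
#' @param maskA,maskB logical matrices (same size).
#' @param meta an [imaging_metadata] (pixel size sets the grid).
#' @param size_range punctum area limits in pixels (default `c(2, 15)`).
#' @param grid_um grid cell edge in micrometers (default 5).
#' @param min_overlap_px overlap must exceed this many pixels (default 4 =
#'   2 x 2).
#' @return list: `percent_colocalized` (weighted average), `per_cell`
#'   data.frame (`grid_r`, `grid_c`, `n_puncta`, `n_colocalized`),
#'   `n_puncta`. NA when no puncta fall in the size range.
#' @export
colocalize_fixed <- function(maskA, maskB, meta = imaging_metadata(0.056),
                             size_range = c(2, 15), grid_um = 5,
                             min_overlap_px = 4) {
  labA <- as.matrix(EBImage::bwlabel(maskA))
  ids <- sort(unique(labA[labA > 0]))
  if (!length(ids))
    return(list(percent_colocalized = NA_real_, per_cell = NULL, n_puncta = 0L))
  grid_px <- grid_um / meta$pixel_size
  rows <- lapply(ids, function(id) {
    px <- which(labA == id, arr.ind = TRUE)
    if (nrow(px) < size_range[1] || nrow(px) > size_range[2]) return(NULL)
    ov <- sum(maskB[px])
    data.frame(grid_r = floor((mean(px[, 1]) - 1) / grid_px),
               grid_c = floor((mean(px[, 2]) - 1) / grid_px),
               coloc = ov > min_overlap_px)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(list(percent_colocalized = NA_real_, per_cell = NULL, n_puncta = 0L))
  agg <- stats::aggregate(coloc ~ grid_r + grid_c, rows,
                          function(v) c(n = length(v), k = sum(v)))
  per_cell <- data.frame(grid_r = agg$grid_r, grid_c = agg$grid_c,
                         n_puncta = agg$coloc[, "n"],
                         n_colocalized = agg$coloc[, "k"])
  pct <- 100 * sum(per_cell$n_colocalized) / sum(per_cell$n_puncta)
  list(percent_colocalized = pct, per_cell = per_cell,
       n_puncta = sum(per_cell$n_puncta))
}

#' Live association between two channels' tracks
#'
#' An A-track is associated with a B-track iff their footprints overlap by
#' more than 1 pixel in some frames and the overlapping period is strictly
#' longer than `min_overlap_s` seconds. The association onset is expressed
#' as a fraction of the A-track's normalized lifetime and binned into a
#' timing profile (where in their lives A-compartments acquire the partner).
#'
#' @param tracksA,tracksB `particle_tracks` objects whose detections carry
#'   footprints: each needs a `footprints` list attribute on `detections`
#'   or `area_px`-sized discs are used around centroids.
#' @param min_overlap_px overlap must exceed this many pixels (default 1).
#' @param min_overlap_s overlap duration must exceed this (default 1 s).
#' @param frame_interval seconds per frame.
#' @param n_bins lifetime-fraction bins for the timing profile (default 5).
#' @return list: `table` per A-track (`track_id`, `associated`,
#'   `onset_fraction`), `profile` (counts per lifetime-fraction bin),
#'   `fraction_associated`.
#' @export
associate_live <- function(tracksA, tracksB, min_overlap_px = 1,
                           min_overlap_s = 1, frame_interval = 1,
                           n_bins = 5) {
  fpA <- track_footprints(tracksA)
  fpB <- track_footprints(tracksB)
  detA <- tracksA$detections; detB <- tracksB$detections
  out <- lapply(sort(unique(detA$track_id)), function(id) {
    rows <- which(detA$track_id == id)
    frames <- detA$frame[rows]
    ov <- logical(length(rows))
    for (k in seq_along(rows)) {
      bs <- which(detB$frame == frames[k])
      if (!length(bs)) next
      a_px <- fpA[[rows[k]]]
      akey <- a_px[, 1] * 1e6 + a_px[, 2]
      for (b in bs) {
        b_px <- fpB[[b]]
        if (sum((b_px[, 1] * 1e6 + b_px[, 2]) %in% akey) > min_overlap_px) {
          ov[k] <- TRUE; break
        }
      }
    }
    runs <- true_runs(ov)
    good <- runs[runs$length * frame_interval > min_overlap_s, , drop = FALSE]
    assoc <- nrow(good) > 0
    onset <- if (assoc) {
      ts <- min(frames); te <- max(frames)
      (frames[good$start[1]] - ts) / max(te - ts, 1)
    } else NA_real_
    data.frame(track_id = id, associated = assoc, onset_fraction = onset)
  })
  tab <- do.call(rbind, out)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  prof <- table(cut(tab$onset_fraction[tab$associated], breaks,
                    include.lowest = TRUE))
  list(table = tab, profile = as.data.frame(prof),
       fraction_associated = mean(tab$associated))
}

# per-detection pixel footprints; falls back to a disc of the detection's
# area around the centroid when explicit footprints are absent
track_footprints <- function(tracks) {
  det <- tracks$detections
  fps <- attr(det, "footprints")
  if (!is.null(fps) && length(fps) == nrow(det)) return(fps)
  lapply(seq_len(nrow(det)), function(i) {
    rad <- max(1, ceiling(sqrt(det$area_px[i] / pi)))
    g <- expand.grid(r = -rad:rad, c = -rad:rad)
    g <- g[g$r^2 + g$c^2 <= rad^2, ]
    cbind(round(det$r[i]) + g$r, round(det$c[i]) + g$c)
  })
}

#' Apical-area rates in the opposing cell around compartment termination
#'
#' For each side-assigned association event, the opposing cell is the
#' interface cell on the side without the compartment; its normalized area
#' rate ([area_rate]) is computed in the `window_s`-second windows before
#' and after the compartment's termination.
#'
#' @param associations data.frame from [associate_tracks] (side required).
#' @param tracked a [tracked_tissue] providing `area_series`.
#' @param window_s window length in seconds (default 30).
#' @return data.frame: `track_id`, `interface_id`, `opposing_cell`,
#'   `pre_rate`, `post_rate` (unitless, 1/s); events whose opposing cell is
#'   not tracked through both windows are skipped.
#' @export
opposing_area_coupling <- function(associations, tracked, window_s = 30) {
  dt <- tracked$metadata$frame_interval
  w <- round(window_s / dt)
  ev <- associations[associations$interface_id != "APICAL" &
                       !is.na(associations$side), , drop = FALSE]
  out <- lapply(seq_len(nrow(ev)), function(i) {
    cells <- as.integer(strsplit(ev$interface_id[i], "|", fixed = TRUE)[[1]])
    opp <- setdiff(cells, ev$side[i])
    if (length(opp) != 1L) return(NULL)
    a <- tracked$area_series[, as.character(opp)]
    t_term <- ev$t_end[i]
    if (t_term - w < 1 || t_term + w > length(a)) return(NULL)
    seg <- a[(t_term - w):(t_term + w)]
    if (anyNA(seg)) return(NULL)
    data.frame(track_id = ev$track_id[i], interface_id = ev$interface_id[i],
               opposing_cell = opp,
               pre_rate = area_rate(a, t_term - w, t_term, dt),
               post_rate = area_rate(a, t_term, t_term + w, dt))
  })
  do.call(rbind, out)
}
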