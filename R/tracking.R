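#' Track segmented frames into a tissue time series
#'
#' Assigns persistent cell identities across frames by maximal pixel-label
#' overlap between consecutive frames (ties broken by smaller centroid
#' displacement, then lower label). Interfaces inherit persistence from their
#' cell pair; per-interface length and per-cell area time series are
#' assembled with explicit NA for frames where an object is absent.
#'
#' @param frames list of [tissue_frame] objects in time order (>= 1).
#' @return an object of class `tracked_tissue` with elements `frames`
#'   (relabelled to persistent ids), `length_series` (frames x interfaces
#'   matrix, micrometers), `area_series` (frames x cells matrix, um^2),
#'   `interface_angles` (same shape as `length_series`, degrees),
#'   `metadata`.
#' @export
track_cells <- function(frames) {
  stopifnot(length(frames) >= 1)
  meta <- frames[[1]]$metadata
  n <- length(frames)
  maps <- vector("list", n)          # frame label -> persistent id
  maps[[1]] <- stats::setNames(frames[[1]]$cells$cell_id,
                               frames[[1]]$cells$cell_id)
  next_id <- max(frames[[1]]$cells$cell_id, 0L) + 1L
  for (t in seq_len(n)[-1]) {
    prev <- frames[[t - 1]]; cur <- frames[[t]]
    ov <- overlap_table(prev$label_image, cur$label_image)
    cur_ids <- cur$cells$cell_id
    assign <- rep(NA_integer_, length(cur_ids))
    claimed <- integer(0)
    any_overlap <- FALSE
    # order current cells by their best overlap, largest first, so the
    # strongest claims win when two cells map to the same predecessor
    best <- vapply(cur_ids, function(cl) {
      o <- ov[ov$cur == cl, ]
      if (!nrow(o)) 0 else max(o$n)
    }, numeric(1))
    for (i in order(-best)) {
      cl <- cur_ids[i]
      o <- ov[ov$cur == cl & !(ov$prev %in% claimed), ]
      if (!nrow(o) || max(o$n) == 0) next
      any_overlap <- TRUE
      cand <- o$prev[o$n == max(o$n)]
      if (length(cand) > 1L) {
        pc <- prev$cells[match(cand, prev$cells$cell_id), ]
        cc <- cur$cells[match(cl, cur$cells$cell_id), ]
        d2 <- (pc$centroid_r - cc$centroid_r)^2 + (pc$centroid_c - cc$centroid_c)^2
        cand <- cand[d2 == min(d2)]
      }
      winner <- min(cand)
      assign[i] <- unname(maps[[t - 1]][as.character(winner)])
      claimed <- c(claimed, winner)
    }
    if (!any_overlap && length(cur_ids) && nrow(prev$cells))
      stop_invalid("no cell overlaps between consecutive frames (scene jump?)",
                   "tracking_failure")
    new <- which(is.na(assign))
    if (length(new)) {
      assign[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    maps[[t]] <- stats::setNames(assign, cur_ids)
  }

  frames <- lapply(seq_len(n), function(t) relabel_frame(frames[[t]], maps[[t]]))

  all_cells <- sort(unique(unlist(lapply(frames, function(f) f$cells$cell_id))))
  all_ints <- sort(unique(unlist(lapply(frames, function(f) f$interfaces$interface_id))))
  area <- matrix(NA_real_, n, length(all_cells),
                 dimnames = list(NULL, as.character(all_cells)))
  len <- ang <- matrix(NA_real_, n, length(all_ints),
                       dimnames = list(NULL, all_ints))
  for (t in seq_len(n)) {
    f <- frames[[t]]
    area[t, as.character(f$cells$cell_id)] <- f$cells$area_um2
    if (nrow(f$interfaces)) {
      len[t, f$interfaces$interface_id] <- f$interfaces$length_um
      ang[t, f$interfaces$interface_id] <- f$interfaces$angle_deg
    }
  }
  structure(list(frames = frames, length_series = len, area_series = area,
                 interface_angles = ang, identity_maps = maps,
                 metadata = meta),
            class = "tracked_tissue")
}

#' @export
print.tracked_tissue <- function(x, ...) {
  cat(sprintf("tracked_tissue: %d frames, %d cells, %d interfaces\n",
              length(x$frames), ncol(x$area_series), ncol(x$length_series)))
  invisible(x)
}

# overlap counts between positive labels of two aligned label images
overlap_table <- function(lab1, lab2) {
  sel <- lab1 > 0L & lab2 > 0L
  if (!any(sel)) return(data.frame(prev = integer(0), cur = integer(0), n = integer(0)))
  K <- max(lab2) + 1
  code <- as.numeric(lab1[sel]) * K + as.numeric(lab2[sel])
  tab <- table(code)
  codes <- as.numeric(names(tab))
  data.frame(prev = as.integer(codes %/% K), cur = as.integer(codes %% K),
             n = as.integer(tab))
}

# rewrite one frame's labels/ids through a label -> persistent-id map
relabel_frame <- function(f, map) {
  lab <- f$label_image
  pos <- lab > 0L
  lab[pos] <- unname(map[as.character(lab[pos])])
  f$label_image <- lab
  f$cells$cell_id <- unname(map[as.character(f$cells$cell_id)])
  f$cells$neighbors <- lapply(f$cells$neighbors, function(v)
    sort(unname(map[as.character(v)])))
  if (nrow(f$interfaces)) {
    a <- unname(map[as.character(f$interfaces$cell_a)])
    b <- unname(map[as.character(f$interfaces$cell_b)])
    f$interfaces$cell_a <- pmin(a, b)
    f$interfaces$cell_b <- pmax(a, b)
    f$interfaces$interface_id <- paste(f$interfaces$cell_a,
                                       f$interfaces$cell_b, sep = "|")
  }
  f
}

#' Neighbor-number distributions over time
#'
#' Per frame, the fraction of interior (non-border) cells with 4-8 neighbors;
#' cells touching the segmented region's edge are excluded because their true
#' neighbor count is unknown. Traces are Gaussian-smoothed in time.
#'
#' @param tracked a [tracked_tissue].
#' @param sigma_s temporal smoothing sigma in seconds (default 5).
#' @return data.frame with columns `frame`, `time_s`, `n4` .. `n8`
#'   (smoothed fractions; NA where a frame has no interior cells), and
#'   attribute `raw` holding the unsmoothed fractions.
#' @export
neighbor_distribution <- function(tracked, sigma_s = 5) {
  nfr <- length(tracked$frames)
  dt <- tracked$metadata$frame_interval
  ns <- 4:8
  raw <- matrix(NA_real_, nfr, length(ns),
                dimnames = list(NULL, paste0("n", ns)))
  for (t in seq_len(nfr)) {
    cells <- tracked$frames[[t]]$cells
    interior <- cells[!cells$touches_border, , drop = FALSE]
    if (!nrow(interior)) next
    counts <- vapply(interior$neighbors, length, integer(1))
    raw[t, ] <- vapply(ns, function(k) mean(counts == k), numeric(1))
  }
  sm <- raw
  if (nfr > 1) {
    sig <- sigma_s / dt
    for (j in seq_len(ncol(sm))) sm[, j] <- gaussian_filter1d(raw[, j], sig)
  }
  out <- data.frame(frame = seq_len(nfr), time_s = (seq_len(nfr) - 1) * dt)
  out <- cbind(out, as.data.frame(sm))
  attr(out, "raw") <- raw
  attr(out, "sigma_s") <- sigma_s
  out
}
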