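# Square linear assignment problem, O(n^3) shortest-augmenting-path
# (Jonker-Volgenant style with potentials). Returns, for each row, the
# assigned column of a minimum-total-cost perfect matching. Forbidden
# assignments should be encoded as large finite costs, not Inf.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

#' Link particle detections into tracks with gap closing
#'
#' Frame-to-frame linking is solved as a rectangular assignment problem
#' minimizing total squared displacement, with birth/death dummy costs of
#' `max_link_dist^2` (a detection prefers a link whenever one within range
#' exists). Track stubs are then joined by a second, globally cost-optimal
#' assignment: the end of one track may be connected to the start of another
#' iff their positions are within `gap_dist` pixels and the time gap is at
#' most `gap_time_s` seconds.
#'
#' @param detections data.frame with columns `frame`, `r`, `c` (as from
#'   [detect_particles_stack]); rows in any order.
#' @param max_link_dist maximum frame-to-frame link distance, pixels.
#' @param gap_dist maximum stub distance for gap closing, pixels
#'   (default 4 px = 0.66 um at 0.164 um/px).
#' @param gap_time_s maximum stub time gap, seconds (default 3).
#' @param frame_interval seconds per frame.
#' @return list of class `particle_tracks`: `detections` (input plus
#'   `track_id`), `tracks` data.frame (`track_id`, `t_start`, `t_end`,
#'   `lifetime_frames`, `lifetime_s`, `n_detections`, `n_gaps_closed`),
#'   `closed_gaps` data.frame (`track_id`, `gap_start`, `gap_end`, `dist_px`).
#' @export
link_tracks <- function(detections, max_link_dist = 5, gap_dist = 4,
                        gap_time_s = 3, frame_interval = 1) {
  det <- detections[order(detections$frame), , drop = FALSE]
  nd <- nrow(det)
  if (nd == 0L)
    return(structure(list(detections = det,
                          tracks = data.frame(track_id = integer(0),
                                              t_start = integer(0), t_end = integer(0),
                                              lifetime_frames = integer(0),
                                              lifetime_s = numeric(0),
                                              n_detections = integer(0),
                                              n_gaps_closed = integer(0)),
                          closed_gaps = data.frame()),
                     class = "particle_tracks"))
  BIG <- 1e12
  det$track_id <- NA_integer_
  next_tid <- 1L
  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nd), det$frame)
  # seed tracks in the first occupied frame
  first <- by_frame[[as.character(frames[1])]]
  det$track_id[first] <- seq_along(first)
  next_tid <- length(first) + 1L
  for (fi in seq_along(frames)[-1]) {
    f_prev <- frames[fi - 1]; f_cur <- frames[fi]
    cur <- by_frame[[as.character(f_cur)]]
    if (f_cur != f_prev + 1L) {      # temporal hole: all births
      det$track_id[cur] <- seq(next_tid, length.out = length(cur))
      next_tid <- next_tid + length(cur)
      next
    }
    prev <- by_frame[[as.character(f_prev)]]
    n <- length(prev); m <- length(cur)
    d2 <- outer(det$r[prev], det$r[cur], "-")^2 +
      outer(det$c[prev], det$c[cur], "-")^2
    link <- ifelse(d2 <= max_link_dist^2, d2, BIG)
    death <- matrix(BIG, n, n); diag(death) <- max_link_dist^2
    birth <- matrix(BIG, m, m); diag(birth) <- max_link_dist^2
    cost <- rbind(cbind(link, death),
                  cbind(birth, matrix(0, m, n)))
    a <- lap_solve(cost)
    for (i in seq_len(n)) {
      j <- a[i]
      if (j <= m && link[i, j] < BIG)
        det$track_id[cur[j]] <- det$track_id[prev[i]]
    }
    born <- cur[is.na(det$track_id[cur])]
    if (length(born)) {
      det$track_id[born] <- seq(next_tid, length.out = length(born))
      next_tid <- next_tid + length(born)
    }
  }

  ## ---- gap closing between track stubs ----
  stub <- function() {
    tid <- sort(unique(det$track_id))
    ts <- vapply(tid, function(id) min(det$frame[det$track_id == id]), numeric(1))
    te <- vapply(tid, function(id) max(det$frame[det$track_id == id]), numeric(1))
    list(tid = tid, ts = ts, te = te)
  }
  s <- stub()
  ends_pos <- t(vapply(s$tid, function(id) {
    i <- which(det$track_id == id & det$frame == s$te[match(id, s$tid)])[1]
    c(det$r[i], det$c[i])
  }, numeric(2)))
  starts_pos <- t(vapply(s$tid, function(id) {
    i <- which(det$track_id == id & det$frame == s$ts[match(id, s$tid)])[1]
    c(det$r[i], det$c[i])
  }, numeric(2)))
  K <- length(s$tid)
  closed <- data.frame(track_id = integer(0), gap_start = integer(0),
                       gap_end = integer(0), dist_px = numeric(0),
                       absorbed = integer(0), into = integer(0))
  if (K > 1) {
    d2 <- outer(ends_pos[, 1], starts_pos[, 1], "-")^2 +
      outer(ends_pos[, 2], starts_pos[, 2], "-")^2
    dtm <- outer(s$te, s$ts, function(e, st) st - e)   # frames from end to start
    ok <- dtm >= 1 & dtm * frame_interval <= gap_time_s &
      d2 <= gap_dist^2 & !diag(TRUE, K)
    if (any(ok)) {
      dummy <- gap_dist^2 + 1
      cost <- ifelse(ok, d2, BIG)
      n2 <- 2L * K
      full <- matrix(BIG, n2, n2)
      full[1:K, 1:K] <- cost
      fr <- full[1:K, (K + 1):n2]; diag(fr) <- dummy; full[1:K, (K + 1):n2] <- fr
      bl <- full[(K + 1):n2, 1:K]; diag(bl) <- dummy; full[(K + 1):n2, 1:K] <- bl
      full[(K + 1):n2, (K + 1):n2] <- 0
      a <- lap_solve(full)
      join_to <- rep(NA_integer_, K)       # end of track k joins start of join_to[k]
      for (k in seq_len(K)) {
        j <- a[k]
        if (j <= K && ok[k, j]) join_to[k] <- j
      }
      # merge chains end -> start
      for (k in seq_len(K)) {
        j <- join_to[k]
        if (is.na(j)) next
        from <- s$tid[k]; to <- s$tid[j]
        # resolve the surviving id of `from` after earlier merges
        root <- from
        while (root %in% closed$absorbed) root <- closed$into[match(root, closed$absorbed)]
        closed <- rbind(closed, data.frame(track_id = root,
                                           gap_start = s$te[k],
                                           gap_end = s$ts[j],
                                           dist_px = sqrt(d2[k, j]),
                                           absorbed = to, into = root))
        det$track_id[det$track_id == to] <- root
      }
    }
  }
  closed$absorbed <- NULL; closed$into <- NULL

  # renumber tracks by first appearance
  tid <- unique(det$track_id[order(det$frame, det$r, det$c)])
  det$track_id <- match(det$track_id, tid)
  if (nrow(closed)) closed$track_id <- match(closed$track_id, tid)
  tr <- do.call(rbind, lapply(sort(unique(det$track_id)), function(id) {
    fi <- det$frame[det$track_id == id]
    data.frame(track_id = id, t_start = min(fi), t_end = max(fi),
               lifetime_frames = max(fi) - min(fi) + 1L,
               lifetime_s = (max(fi) - min(fi) + 1L) * frame_interval,
               n_detections = length(fi),
               n_gaps_closed = if (nrow(closed)) sum(closed$track_id == id) else 0L)
  }))
  structure(list(detections = det, tracks = tr, closed_gaps = closed),
            class = "particle_tracks")
}

#' @export
print.particle_tracks <- function(x, ...) {
  cat(sprintf("particle_tracks: %d tracks from %d detections (%d gaps closed)\n",
              nrow(x$tracks), nrow(x$detections), nrow(x$closed_gaps)))
  invisible(x)
}

#' Track lifetimes with finite-movie correction
#'
#' Lifetime = (t_end - t_start) + 1 frames, times the frame interval. Tracks
#' touching the first or last movie frame are flagged censored (their true
#' lifetime is unknown). With `correct = TRUE` the distribution over
#' uncensored tracks is reweighted by the inverse number of movie positions
#' at which a track of that length could have been fully observed,
#' 1 / (movie_length - lifetime_frames + 1), removing the finite-window bias
#' against long lifetimes (exact when initiations are uniform in time over
#' the movie).
#'
#' @param tracks `tracks` data.frame from [link_tracks] (or any frame with
#'   `t_start`, `t_end`).
#' @param movie_length movie length in frames.
#' @param frame_interval seconds per frame.
#' @param correct apply the finite-window reweighting (default TRUE).
#' @return list: `table` (per-track lifetimes with `censored`, `weight`),
#'   `mean_lifetime_s` (corrected if requested), `naive_mean_lifetime_s`.
#' @export
track_lifetimes <- function(tracks, movie_length, frame_interval = 1,
                            correct = TRUE) {
  L <- tracks$t_end - tracks$t_start + 1L
  cens <- tracks$t_start <= 1L | tracks$t_end >= movie_length
  w <- rep(1, length(L))
  if (correct) w <- 1 / pmax(movie_length - L + 1, 1)
  tab <- data.frame(track_id = if ("track_id" %in% names(tracks)) tracks$track_id
                    else seq_along(L),
                    t_start = tracks$t_start, t_end = tracks$t_end,
                    lifetime_frames = L, lifetime_s = L * frame_interval,
                    censored = cens, weight = w)
  use <- !cens
  mean_life <- if (any(use))
    sum(w[use] * L[use] * frame_interval) / sum(w[use]) else NA_real_
  list(table = tab,
       mean_lifetime_s = mean_life,
       naive_mean_lifetime_s = if (any(use)) mean(L[use]) * frame_interval else NA_real_)
}

#' Drop short spurious tracks
#'
#' Tracks supported by fewer than `min_detections` detections are removed
#' (isolated noise detections form 1-frame tracks); track ids are preserved.
#'
#' @param tracks a `particle_tracks` object.
#' @param min_detections minimum detections per track (default 3).
#' @return a filtered `particle_tracks`.
#' @export
filter_tracks <- function(tracks, min_detections = 3L) {
  keep <- tracks$tracks$track_id[tracks$tracks$n_detections >= min_detections]
  det_keep <- tracks$detections$track_id %in% keep
  fps <- attr(tracks$detections, "footprints")
  tracks$detections <- tracks$detections[det_keep, , drop = FALSE]
  if (!is.null(fps)) attr(tracks$detections, "footprints") <- fps[det_keep]
  tracks$tracks <- tracks$tracks[tracks$tracks$track_id %in% keep, , drop = FALSE]
  if (nrow(tracks$closed_gaps))
    tracks$closed_gaps <- tracks$closed_gaps[tracks$closed_gaps$track_id %in% keep, , drop = FALSE]
  tracks
}
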