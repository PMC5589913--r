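# Shared fixtures, all generated in code.

# three mutually adjacent rectangular-ish cells in a 30 x 30 field
three_cell_labels <- function() {
  lab <- matrix(0L, 30, 30)
  lab[2:29, 2:15] <- 1L
  lab[2:15, 16:29] <- 2L
  lab[16:29, 16:29] <- 3L
  lab
}

# hexagonal-ish brick lattice: rows of cells offset by half a cell, so every
# interior vertex is 3-fold and interior cells have 6 neighbors
brick_labels <- function(n_rows = 5, n_cols = 5, w = 12L, h = 10L) {
  H <- n_rows * h + 2L; W <- n_cols * w + 2L
  lab <- matrix(0L, H, W)
  id <- 0L
  for (i in seq_len(n_rows)) {
    off <- if (i %% 2 == 0) w %/% 2L else 0L
    edges <- unique(pmin(pmax(c(0L, seq(off, W - 2L, by = w), W - 2L), 0L), W - 2L))
    edges <- sort(unique(edges))
    for (k in seq_len(length(edges) - 1L)) {
      id <- id + 1L
      rs <- ((i - 1L) * h + 2L):(i * h + 1L)
      cs <- (edges[k] + 2L):(edges[k + 1L] + 1L)
      lab[rs, cs] <- id
    }
  }
  lab
}

# brute-force MSD: the displayed definition, double loop
msd_bruteforce <- function(x, max_lag) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  N <- nrow(x)
  vapply(seq_len(max_lag), function(n) {
    s <- 0
    for (k in 1:(N - n)) s <- s + sum((x[k + n, ] - x[k, ])^2)
    s / (N - n)
  }, numeric(1))
}

# brute-force association oracle: literal rule checking with plain loops
associate_oracle <- function(centroid, frame, dist_cutoff = 10) {
  ints <- frame$interfaces
  if (!nrow(ints)) return("APICAL")
  d <- numeric(nrow(ints))
  for (i in seq_len(nrow(ints))) {
    px <- ints$contour[[i]]
    best <- Inf
    for (k in seq_len(nrow(px))) {
      dd <- sqrt((px[k, 1] - centroid[1])^2 + (px[k, 2] - centroid[2])^2)
      if (dd < best) best <- dd
    }
    d[i] <- best
  }
  i_best <- which.min(d)
  if (d[i_best] > dist_cutoff) return("APICAL")           # rule (i)
  others <- d[-i_best]
  if (length(others) && min(others) - d[i_best] <= 1e-9)  # rule (ii)
    return("APICAL")
  vids <- c(ints$vertex_1[i_best], ints$vertex_2[i_best])
  vids <- vids[!is.na(vids)]
  if (length(vids)) {
    vv <- frame$vertices[frame$vertices$vertex_id %in% vids, ]
    dv <- Inf
    for (k in seq_len(nrow(vv)))
      dv <- min(dv, sqrt((vv$r[k] - centroid[1])^2 + (vv$c[k] - centroid[2])^2))
    if (dv < min(1, 0.1 * ints$length_px[i_best]))        # rule (iii)
      return("APICAL")
  }
  ints$interface_id[i_best]
}
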