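# Seed handling: every generator takes an integer seed and uses R's RNG
# locally, restoring the caller's RNG state afterwards, so identical seeds
# give identical output without disturbing the session.
with_seed <- function(seed, expr) {
  force(seed)  # draw any caller-supplied random seed before saving state
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate interface-length trajectories with known MSD components
#'
#' Each trajectory is the sum of a mean-reverting confined component
#' (discrete Ornstein-Uhlenbeck with stationary MSD plateau A and
#' relaxation rate alpha), a Brownian component with diffusion coefficient
#' B, a piecewise-ballistic active component moving at speed C during
#' prescribed runs, and i.i.d. Gaussian localization noise. The generated
#' ensemble's MSD follows A(1 - exp(-alpha tau)) + 2 B tau + C^2 tau^2
#' during homogeneous motion.
#'
#' @param n number of trajectories.
#' @param N frames per trajectory.
#' @param A confined plateau amplitude (um^2).
#' @param alpha confinement relaxation rate (1/s).
#' @param B diffusion coefficient (um^2/s).
#' @param C active speed during runs (um/s).
#' @param noise_sd localization noise sd (um).
#' @param frame_interval seconds per frame.
#' @param runs either `NULL` (no active runs; C acts continuously if > 0...
#'   see Details), or a list `list(n_runs=, duration=, mode=)` with mode
#'   `"control"` (all runs contract, negative displacement) or
#'   `"ratchet_off"` (runs alternate sign, near-zero net displacement);
#'   runs are placed uniformly without overlap, separated by >= 5 frames.
#' @param baseline starting value (um), default 10.
#' @param seed integer seed.
#' @details With `runs = NULL` and `C > 0` the ballistic drift acts over the
#'   whole trajectory (pure-drift calibration input). With a `runs` spec the
#'   drift acts only inside the runs and `C` elsewhere contributes nothing.
#' @return list: `trajectories` (N x n matrix, um), `truth` (list with
#'   per-trajectory `runs` data.frames: `start`, `end`, `sign`,
#'   `displacement_um`), `params`.
#' @export
synth_trajectories <- function(n, N, A = 0, alpha = 0.05, B = 0, C = 0,
                               noise_sd = 0, frame_interval = 1,
                               runs = NULL, baseline = 10, seed = 1) {
  with_seed(seed, {
    dt <- frame_interval
    traj <- matrix(0, N, n)
    truth_runs <- vector("list", n)
    rho <- exp(-alpha * dt)
    sd_ou <- sqrt(pmax(A / 2 * (1 - rho^2), 0))
    sd_bm <- sqrt(2 * B * dt)
    for (j in seq_len(n)) {
      ou <- numeric(N)
      if (A > 0) {
        ou[1] <- stats::rnorm(1, 0, sqrt(A / 2))
        eps <- stats::rnorm(N - 1, 0, sd_ou)
        for (t in 2:N) ou[t] <- rho * ou[t - 1] + eps[t - 1]
      }
      bm <- if (B > 0) cumsum(c(0, stats::rnorm(N - 1, 0, sd_bm))) else numeric(N)
      drift <- numeric(N)
      rn <- data.frame(start = integer(0), end = integer(0), sign = integer(0),
                       displacement_um = numeric(0))
      if (is.null(runs)) {
        if (C > 0) drift <- (seq_len(N) - 1) * C * dt
      } else {
        k <- runs$n_runs; dur <- runs$duration
        mode <- if (is.null(runs$mode)) "control" else runs$mode
        starts <- place_runs(N, k, dur, margin = 5L)
        sgn <- if (mode == "ratchet_off") rep_len(c(-1L, 1L), length(starts))
               else rep(-1L, length(starts))
        vel <- numeric(N)
        for (q in seq_along(starts)) {
          idx <- starts[q]:(starts[q] + dur - 1L)
          vel[idx] <- sgn[q] * C
        }
        drift <- cumsum(c(0, vel[-N] * dt))
        rn <- data.frame(start = starts, end = starts + dur - 1L, sign = sgn,
                         displacement_um = sgn * C * dt * (dur - 1L))
      }
      noise <- if (noise_sd > 0) stats::rnorm(N, 0, noise_sd) else numeric(N)
      traj[, j] <- baseline + ou + bm + drift + noise
      truth_runs[[j]] <- rn
    }
    list(trajectories = traj, truth = list(runs = truth_runs),
         params = list(A = A, alpha = alpha, B = B, C = C,
                       noise_sd = noise_sd, frame_interval = dt, seed = seed))
  })
}

# k non-overlapping run starts of length dur in 1..N, pairwise separated by
# >= margin frames; deterministic given the RNG state
place_runs <- function(N, k, dur, margin = 5L) {
  slots <- N - k * (dur + margin)
  if (slots < 0) stop_invalid("active runs do not fit the trajectory", "invalid_input")
  gaps <- stats::rmultinom(1, slots, rep(1, k + 1))[, 1]
  starts <- integer(k)
  pos <- 1L + margin %/% 2L
  for (q in seq_len(k)) {
    pos <- pos + gaps[q]
    starts[q] <- pos
    pos <- pos + dur + margin
  }
  starts
}

#' Generate a ground-truthed polygonal cell-sheet movie
#'
#' A kinematic quadrilateral lattice: cells sit in `n_rows` x `n_cols`
#' bands, every vertical interface's length is independently prescribed
#' through time (contractile staircase dynamics plus optional sinusoidal
#' area oscillation), and each frame is rendered as a label image plus a
#' noisy membrane-channel image. The first and last cell rows absorb the
#' slack so the sheet always tiles the field of view.
#'
#' Modes: `control` - monotone negative steps with pauses (progressive
#' contraction); `ratchet_off` - steps of alternating sign (contractions
#' that reverse; near-zero net stepped displacement); `furrow` - no steps,
#' central rows' apical areas decay to `furrow_final_frac` over the movie.
#'
#' @param mode `"control"`, `"ratchet_off"`, or `"furrow"`.
#' @param n_rows,n_cols cells per column/row of the lattice.
#' @param n_frames movie length in frames.
#' @param cell_px nominal cell edge in pixels (default 24).
#' @param amplitude_pct sinusoidal relative area amplitude (percent of the
#'   local mean; default 0 = no oscillation).
#' @param period_s oscillation period in seconds (default 120).
#' @param n_steps,step_um,step_frames stepped-contraction parameters per
#'   interior vertical interface (defaults 3 steps of 1 um over 20 frames).
#' @param furrow_final_frac final area fraction of central rows in furrow
#'   mode (default 0.5).
#' @param membrane_noise_sd Gaussian noise sd on the membrane channel
#'   (signal scale 0..1; default 0.05).
#' @param meta an [imaging_metadata].
#' @param seed integer seed.
#' @return list of class `synthetic_tissue`: `labels` (list of integer label
#'   matrices), `membrane` (list of numeric matrices), `truth` (list:
#'   `length_series_um` frames x interfaces for interior vertical
#'   interfaces, `area_series_um2` frames x cells, `steps` data.frame,
#'   `amplitude_pct`, `seed`), `meta`.
#' @export
synth_tissue <- function(mode = c("control", "ratchet_off", "furrow"),
                         n_rows = 4, n_cols = 4, n_frames = 120,
                         cell_px = 24, amplitude_pct = 0, period_s = 120,
                         n_steps = 3, step_um = 1, step_frames = 20,
                         furrow_final_frac = 0.5, membrane_noise_sd = 0.05,
                         meta = imaging_metadata(), seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    dt <- meta$frame_interval
    margin <- 0   # the sheet tiles the whole field of view
    W <- n_cols * cell_px + 2 * margin
    H <- n_rows * cell_px + 2 * margin
    X <- margin + (0:n_cols) * cell_px          # column lines, x = px units
    # base heights per (row band i = 1..n_rows, column line j = 0..n_cols)
    h0 <- cell_px
    step_px <- step_um / meta$pixel_size

    # prescribed height h[i, j, t] for interior bands i = 2..(n_rows-1);
    # bands 1 and n_rows absorb slack
    interior <- if (n_rows >= 3) 2:(n_rows - 1) else integer(0)
    nJ <- n_cols + 1
    hs <- array(h0, dim = c(n_rows, nJ, n_frames))
    steps_truth <- NULL
    phase <- matrix(stats::runif(n_rows * nJ, 0, 2 * pi), n_rows, nJ)
    a_rel <- amplitude_pct / 100
    tt <- (seq_len(n_frames) - 1) * dt
    for (i in seq_len(n_rows)) for (j in seq_len(nJ)) {
      base <- rep(h0, n_frames)
      if (i %in% interior && j >= 2 && j <= n_cols && mode != "furrow" &&
          n_steps > 0 && step_px > 0) {
        starts <- place_runs(n_frames, n_steps, step_frames, margin = 8L)
        sgn <- if (mode == "ratchet_off") rep_len(c(-1, 1), n_steps) else rep(-1, n_steps)
        vel <- numeric(n_frames)
        for (q in seq_along(starts))
          vel[starts[q]:(starts[q] + step_frames - 1L)] <- sgn[q] * step_px / step_frames
        base <- base + cumsum(c(0, vel[-n_frames]))
        # keep geometry feasible
        base <- pmax(base, 2)
        iface <- sprintf("v_r%d_c%d", i, j - 1)
        steps_truth <- rbind(steps_truth, data.frame(
          interface_id = iface, start = starts, end = starts + step_frames - 1L,
          sign = sgn, displacement_um = sgn * step_px * meta$pixel_size *
            (step_frames - 1L) / step_frames))
      }
      if (mode == "furrow" && i %in% interior) {
        frac <- 1 - (1 - furrow_final_frac) * (tt / max(tt))
        base <- base * frac
      }
      if (a_rel > 0)
        base <- base * (1 + a_rel * sin(2 * pi * tt / period_s + phase[i, j]))
      hs[i, j, ] <- base
    }

    labels <- vector("list", n_frames)
    membrane <- vector("list", n_frames)
    # interior vertical interfaces: bands 2..n_rows-1 at column lines 1..n_cols-1
    ifc_ids <- as.vector(outer(interior, seq_len(n_cols - 1),
                               function(i, j) sprintf("v_r%d_c%d", i, j)))
    len_um <- matrix(NA_real_, n_frames, length(ifc_ids),
                     dimnames = list(NULL, ifc_ids))
    cell_ids <- as.vector(outer(seq_len(n_rows), seq_len(n_cols),
                                function(i, j) sprintf("cell_r%d_c%d", i, j)))
    area_um2 <- matrix(NA_real_, n_frames, length(cell_ids),
                       dimnames = list(NULL, cell_ids))
    vertex_y <- vector("list", n_frames)

    for (t in seq_len(n_frames)) {
      # stack heights into y boundaries per column line; slack into bands 1, n
      y <- matrix(0, n_rows + 1, nJ)
      for (j in seq_len(nJ)) {
        h <- hs[, j, t]
        slack <- (H - 2 * margin) - sum(h[interior])
        nb <- n_rows - length(interior)
        h[-interior] <- slack / max(nb, 1)
        if (!length(interior)) h <- rep((H - 2 * margin) / n_rows, n_rows)
        y[1, j] <- margin
        for (i in seq_len(n_rows)) y[i + 1, j] <- y[i, j] + h[i]
      }
      vertex_y[[t]] <- y
      # truth: interface lengths and areas
      for (i in interior) for (j in seq_len(n_cols - 1)) {
        len_um[t, sprintf("v_r%d_c%d", i, j)] <-
          (y[i + 1, j + 1] - y[i, j + 1]) * meta$pixel_size
      }
      for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
        hl <- y[i + 1, j] - y[i, j]
        hr <- y[i + 1, j + 1] - y[i, j + 1]
        area_um2[t, sprintf("cell_r%d_c%d", i, j)] <-
          cell_px * (hl + hr) / 2 * meta$pixel_size^2
      }
      if (t > 1 && identical(y, vertex_y[[t - 1]])) {
        labels[[t]] <- labels[[t - 1]]      # static geometry: reuse raster
        base <- attr(membrane[[t - 1]], "base")
      } else {
        labels[[t]] <- render_lattice(y, X, W, H, n_rows, n_cols)
        base <- render_membrane_base(labels[[t]])
      }
      m <- base
      if (membrane_noise_sd > 0)
        m <- m + matrix(stats::rnorm(H * W, 0, membrane_noise_sd), H, W)
      attr(m, "base") <- base
      membrane[[t]] <- m
    }
    structure(list(labels = labels, membrane = membrane,
                   truth = list(length_series_um = len_um,
                                area_series_um2 = area_um2,
                                steps = steps_truth,
                                vertex_y = vertex_y, X = X,
                                amplitude_pct = amplitude_pct,
                                period_s = period_s, mode = mode, seed = seed),
                   meta = meta),
              class = "synthetic_tissue")
  })
}

# rasterize the quad lattice: pixel (r, c) -> cell label, 0 = background
render_lattice <- function(y, X, W, H, n_rows, n_cols) {
  lab <- matrix(0L, H, W)
  cx <- seq_len(W) - 0.5
  jc <- findInterval(cx, X)                 # 0 = left margin, n_cols+1 = right
  for (c in seq_len(W)) {
    j <- jc[c]
    if (j < 1 || j > n_cols) next
    x0 <- X[j]; x1 <- X[j + 1]
    f <- (cx[c] - x0) / (x1 - x0)
    yb <- y[, j] * (1 - f) + y[, j + 1] * f   # boundary y at this x
    ry <- seq_len(H) - 0.5
    band <- findInterval(ry, yb)              # 0 above sheet, n_rows+1 below
    inside <- band >= 1 & band <= n_rows
    lab[inside, c] <- (band[inside] - 1L) * n_cols + j
  }
  storage.mode(lab) <- "integer"
  lab
}

# noise-free membrane channel: bright blurred cell boundaries
render_membrane_base <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  dif_v <- lab[-nr, , drop = FALSE] != lab[-1, , drop = FALSE]
  dif_h <- lab[, -nc, drop = FALSE] != lab[, -1, drop = FALSE]
  edge <- matrix(0, nr, nc)
  edge[-nr, ][dif_v] <- 1; edge[-1, ][dif_v] <- 1
  edge[, -nc][dif_h] <- 1; edge[, -1][dif_h] <- 1
  0.1 + 0.8 * as.matrix(EBImage::gblur(edge, sigma = 1))
}

#' Render a compartment (spot) channel movie with known ground truth
#'
#' Places transient bright compartments either on the interfaces of a
#' [synth_tissue] lattice (a prescribed fraction on vertical interfaces -
#' the planar polarity of the generated movie - and the rest split between
#' horizontal interfaces and the open apical surface) or, without a lattice,
#' at uniformly random positions. Each spot's intensity follows a
#' grow-then-shrink triangular profile (peak at 60 percent of its lifetime)
#' over a drawn lifetime, rendered as a Gaussian footprint over a noisy
#' background whose peak amplitude is `snr` times the background noise sd.
#'
#' @param n_spots number of compartments.
#' @param n_frames movie length in frames.
#' @param dim_px image size `c(rows, cols)`; taken from the lattice when one
#'   is given.
#' @param lattice optional `synthetic_tissue` (its final-frame geometry is
#'   used for placement).
#' @param polarity_fraction fraction of spots on vertical interfaces
#'   (default 0.57); of the remainder, half go to horizontal interfaces and
#'   half to the apical surface (cell centers). Ignored without a lattice.
#' @param lifetime_mean_s mean of the exponential lifetime law (seconds);
#'   or use `lifetime_const_s` for a constant lifetime.
#' @param lifetime_const_s if non-NULL, every lifetime is this constant.
#' @param snr peak spot amplitude over background noise sd (Inf = noiseless).
#' @param profile_floor minimum of the grow/shrink intensity profile as a
#'   fraction of peak (default 0.3): a compartment stays visible over its
#'   whole lifetime, as lifetimes are defined by visibility.
#' @param spot_sigma_px Gaussian footprint sd in pixels (default 2).
#' @param background background intensity level (default 10).
#' @param frame_interval seconds per frame.
#' @param seed integer seed.
#' @return list of class `synthetic_spots`: `stack` (list of matrices),
#'   `truth` data.frame (`spot_id`, `t_start`, `t_end`, `lifetime_frames`,
#'   `r`, `c`, `placement` (vertical/horizontal/apical), `interface_id`,
#'   `side`), `params`.
#' @export
synth_spot_movie <- function(n_spots, n_frames, dim_px = c(128, 128),
                             lattice = NULL, polarity_fraction = 0.57,
                             lifetime_mean_s = 30, lifetime_const_s = NULL,
                             snr = 10, profile_floor = 0.3,
                             spot_sigma_px = 2, background = 10,
                             frame_interval = 1, seed = 1) {
  if (!is.finite(snr) && !identical(snr, Inf))
    stop_invalid("snr must be positive or Inf", "invalid_input")
  with_seed(seed, {
    if (!is.null(lattice)) {
      lab1 <- lattice$labels[[1]]
      dim_px <- dim(lab1)
      y <- lattice$truth$vertex_y[[1]]
      X <- lattice$truth$X
      n_rows <- nrow(y) - 1L; n_cols <- length(X) - 1L
    }
    H <- dim_px[1]; W <- dim_px[2]
    noise_sd <- if (is.finite(snr)) 1 else 0
    amp <- if (is.finite(snr)) snr * noise_sd else 10
    placement <- rep("apical", n_spots)
    pos <- matrix(0, n_spots, 2)
    iface <- rep(NA_character_, n_spots)
    side <- rep(NA_character_, n_spots)
    if (!is.null(lattice)) {
      # realize the prescribed composition exactly: round(pf n) vertical,
      # the remainder split between horizontal interfaces and the apical
      # surface, in shuffled order
      n_v <- round(polarity_fraction * n_spots)
      n_h <- round((n_spots - n_v) / 2)
      placement <- sample(c(rep("vertical", n_v), rep("horizontal", n_h),
                            rep("apical", n_spots - n_v - n_h)))
      interior <- if (n_rows >= 3) 2:(n_rows - 1) else seq_len(n_rows)
      for (s in seq_len(n_spots)) {
        if (placement[s] == "vertical") {
          i <- sample(interior, 1); j <- sample(seq_len(n_cols - 1), 1)
          frac <- stats::runif(1, 0.3, 0.7)     # clear of both vertices
          ry <- y[i, j + 1] + frac * (y[i + 1, j + 1] - y[i, j + 1])
          off <- sample(c(-1.5, 1.5), 1)        # which cell's surface
          pos[s, ] <- c(ry, X[j + 1] + off)
          iface[s] <- sprintf("v_r%d_c%d", i, j)
          side[s] <- if (off < 0) sprintf("cell_r%d_c%d", i, j)
                     else sprintf("cell_r%d_c%d", i, j + 1)
        } else if (placement[s] == "horizontal") {
          i <- sample(seq_len(n_rows - 1), 1); j <- sample(seq_len(n_cols), 1)
          frac <- stats::runif(1, 0.3, 0.7)
          rx <- X[j] + frac * (X[j + 1] - X[j])
          f <- (rx - X[j]) / (X[j + 1] - X[j])
          ry <- y[i + 1, j] * (1 - f) + y[i + 1, j + 1] * f
          pos[s, ] <- c(ry + sample(c(-1.5, 1.5), 1), rx)
          iface[s] <- sprintf("h_r%d_c%d", i, j)
        } else {
          i <- sample(seq_len(n_rows), 1); j <- sample(seq_len(n_cols), 1)
          cy <- (y[i, j] + y[i + 1, j] + y[i, j + 1] + y[i + 1, j + 1]) / 4
          cx <- (X[j] + X[j + 1]) / 2
          pos[s, ] <- c(cy, cx)
        }
      }
    } else {
      m <- ceiling(4 * spot_sigma_px)
      pos[, 1] <- stats::runif(n_spots, m + 1, H - m)
      pos[, 2] <- stats::runif(n_spots, m + 1, W - m)
    }
    life <- if (!is.null(lifetime_const_s))
      rep(round(lifetime_const_s / frame_interval), n_spots)
    else pmax(3L, round(stats::rexp(n_spots, 1 / lifetime_mean_s) / frame_interval))
    life <- pmin(life, n_frames)
    t_start <- vapply(life, function(L)
      sample.int(max(n_frames - L + 1L, 1L), 1), integer(1))
    t_end <- pmin(t_start + life - 1L, n_frames)

    stack <- lapply(seq_len(n_frames), function(t) matrix(background, H, W))
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (s in seq_len(n_spots)) {
      L <- t_end[s] - t_start[s] + 1L
      peak_at <- max(1L, round(0.6 * L))
      for (t in t_start[s]:t_end[s]) {
        k <- t - t_start[s] + 1L
        prof <- if (k <= peak_at) k / peak_at
                else (L - k) / max(L - peak_at, 1)
        prof <- max(prof, profile_floor)        # visible over the whole life
        lo_r <- max(1, floor(pos[s, 1] - 4 * spot_sigma_px))
        hi_r <- min(H, ceiling(pos[s, 1] + 4 * spot_sigma_px))
        lo_c <- max(1, floor(pos[s, 2] - 4 * spot_sigma_px))
        hi_c <- min(W, ceiling(pos[s, 2] + 4 * spot_sigma_px))
        g <- amp * prof * exp(-(((rr[lo_r:hi_r, lo_c:hi_c] - pos[s, 1])^2 +
                                   (cc[lo_r:hi_r, lo_c:hi_c] - pos[s, 2])^2) /
                                  (2 * spot_sigma_px^2)))
        stack[[t]][lo_r:hi_r, lo_c:hi_c] <- stack[[t]][lo_r:hi_r, lo_c:hi_c] + g
      }
    }
    if (noise_sd > 0) {
      for (t in seq_len(n_frames))
        stack[[t]] <- stack[[t]] +
          matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    }
    structure(list(stack = stack,
                   truth = data.frame(spot_id = seq_len(n_spots),
                                      t_start = t_start, t_end = t_end,
                                      lifetime_frames = t_end - t_start + 1L,
                                      r = pos[, 1], c = pos[, 2],
                                      placement = placement,
                                      interface_id = iface, side = side),
                   params = list(polarity_fraction = polarity_fraction,
                                 snr = snr, spot_sigma_px = spot_sigma_px,
                                 background = background,
                                 frame_interval = frame_interval, seed = seed)),
              class = "synthetic_spots")
  })
}
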