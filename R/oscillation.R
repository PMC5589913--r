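#' Smooth and detrend an apical-area series
#'
#' The area trajectory is polynomial-smoothed with a Savitzky-Golay filter
#' (order 3, window 81 frames by default) to remove noise-associated
#' oscillations, then detrended by subtracting a long-timescale Gaussian
#' filtered version of itself (sigma 200 s). The Gaussian-filtered signal is
#' the local average area against which amplitudes are expressed.
#'
#' @param area numeric vector of areas (um^2), uniformly sampled.
#' @param frame_interval seconds per frame.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   (frames; odd). If the series is shorter than `sg_window`, the window
#'   shrinks to the largest odd length <= N with a warning.
#' @param trend_sigma_s Gaussian trend sigma in seconds (default 200).
#' @return list with `filtered`, `detrended`, `trend` vectors.
#' @export
smooth_and_detrend <- function(area, frame_interval = 1, sg_order = 3,
                               sg_window = 81, trend_sigma_s = 200) {
  N <- length(area)
  if (N < sg_window) {
    sg_window <- if (N %% 2 == 1) N else N - 1L
    if (sg_window <= sg_order)
      stop_invalid("series too short to smooth", "invalid_input")
    warning(sprintf("series shorter than Savitzky-Golay window; shrunk to %d",
                    sg_window))
  }
  filtered <- as.numeric(signal::sgolayfilt(area, p = sg_order, n = sg_window))
  trend <- gaussian_filter1d(filtered, trend_sigma_s / frame_interval)
  list(filtered = filtered, detrended = filtered - trend, trend = trend)
}

#' Instantaneous oscillation amplitude via the analytic-signal envelope
#'
#' The envelope of the analytic signal (Hilbert method) of the detrended
#' area gives the instantaneous oscillation amplitude, expressed as a
#' percentage of the local average area (the trend) at each instant; the
#' per-cell value is the mean over the cell's full time course. To tame edge
#' transients the detrended signal is mirror-padded by half the dominant
#' period before the transform.
#'
#' @param detrended,trend as returned by [smooth_and_detrend].
#' @return list of class `oscillation_result`: `amplitude_pct` per frame,
#'   `mean_amplitude_pct`, `trend`.
#' @export
instantaneous_amplitude <- function(detrended, trend) {
  if (any(trend <= 0))
    stop_invalid("trend must be positive everywhere", "numeric_domain")
  N <- length(detrended)
  pad <- min(N - 1L, max(1L, dominant_halfperiod(detrended)))
  xp <- c(rev(detrended[2:(pad + 1L)]), detrended, rev(detrended[(N - pad):(N - 1L)]))
  env <- Mod(analytic_signal(xp))[(pad + 1L):(pad + N)]
  amp <- env / trend * 100
  structure(list(amplitude_pct = amp, mean_amplitude_pct = mean(amp),
                 trend = trend),
            class = "oscillation_result")
}

# half the dominant oscillation period, in frames, from the FFT peak
dominant_halfperiod <- function(x) {
  N <- length(x)
  if (N < 8) return(1L)
  sp <- Mod(stats::fft(x - mean(x)))[2:(N %/% 2)]
  k <- which.max(sp)           # cycles over the record
  as.integer(round(N / k / 2))
}

#' Per-cell oscillation amplitudes for a set of area series
#'
#' Convenience wrapper: smooth, detrend and envelope each cell's area
#' trajectory, returning the per-cell mean amplitude percentage.
#'
#' @param area_series frames x cells matrix of areas (um^2; NA allowed at
#'   the ends, trimmed per cell).
#' @param frame_interval seconds per frame.
#' @param ... passed to [smooth_and_detrend].
#' @return data.frame `cell`, `mean_amplitude_pct`, `n_frames`.
#' @export
oscillation_amplitudes <- function(area_series, frame_interval = 1, ...) {
  cells <- colnames(area_series)
  if (is.null(cells)) cells <- as.character(seq_len(ncol(area_series)))
  out <- lapply(seq_len(ncol(area_series)), function(j) {
    a <- area_series[, j]
    ok <- which(!is.na(a))
    if (length(ok) < 8) return(data.frame(cell = cells[j],
                                          mean_amplitude_pct = NA_real_,
                                          n_frames = length(ok)))
    a <- a[min(ok):max(ok)]
    sd <- suppressWarnings(smooth_and_detrend(a, frame_interval, ...))
    r <- instantaneous_amplitude(sd$detrended, sd$trend)
    data.frame(cell = cells[j], mean_amplitude_pct = r$mean_amplitude_pct,
               n_frames = length(a))
  })
  do.call(rbind, out)
}

#' Normalized rate of area change
#'
#' Rate of area change over a window, normalized to the average area over
#' that window: `[A(t_end) - A(t_start)] / (t_end - t_start) / mean(A)`,
#' yielding a unitless rate (1/s). Negative values indicate contraction.
#'
#' @param area numeric area series (um^2).
#' @param t_start,t_end window endpoints in frames (1-based, within series).
#' @param frame_interval seconds per frame.
#' @return unitless rate (1/s).
#' @export
area_rate <- function(area, t_start, t_end, frame_interval = 1) {
  if (t_end <= t_start || t_start < 1 || t_end > length(area))
    stop_invalid("invalid rate window", "invalid_window")
  seg <- area[t_start:t_end]
  (area[t_end] - area[t_start]) / ((t_end - t_start) * frame_interval) /
    mean(seg, na.rm = TRUE)
}

#' Ventral-furrow constriction summary
#'
#' Each cell's area trajectory is normalized to 100% at t = 0 and the
#' cohort mean and standard error are computed per frame; the per-cell
#' constriction rate is (final - initial) percent area over the full
#' duration (default 6.6 min), again averaged with standard error.
#'
#' @param area_series frames x cells matrix of areas (um^2).
#' @param frame_interval seconds per frame.
#' @param duration_min analysis duration in minutes (default 6.6).
#' @return list: `trajectory` data.frame (`time_s`, `mean_pct`, `se_pct`),
#'   `rates` data.frame (`cell`, `rate_pct_per_min`), `mean_rate_pct_per_min`,
#'   `se_rate_pct_per_min`, `excluded` (cells lacking a t = 0 sample).
#' @export
ventral_furrow_summary <- function(area_series, frame_interval = 1,
                                   duration_min = 6.6) {
  n_frames <- min(nrow(area_series), round(duration_min * 60 / frame_interval) + 1)
  cells <- colnames(area_series)
  if (is.null(cells)) cells <- as.character(seq_len(ncol(area_series)))
  keep <- !is.na(area_series[1, ])
  excluded <- cells[!keep]
  if (length(excluded))
    message("excluding cells with no t=0 sample: ", paste(excluded, collapse = ", "))
  A <- area_series[seq_len(n_frames), keep, drop = FALSE]
  pct <- sweep(A, 2, A[1, ], "/") * 100
  mean_pct <- rowMeans(pct, na.rm = TRUE)
  se_pct <- apply(pct, 1, function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  dur_min <- (n_frames - 1) * frame_interval / 60
  rates <- (pct[n_frames, ] - pct[1, ]) / dur_min
  list(trajectory = data.frame(time_s = (seq_len(n_frames) - 1) * frame_interval,
                               mean_pct = mean_pct, se_pct = se_pct),
       rates = data.frame(cell = cells[keep], rate_pct_per_min = rates),
       mean_rate_pct_per_min = mean(rates),
       se_rate_pct_per_min = stats::sd(rates) / sqrt(length(rates)),
       excluded = excluded)
}

#' Interface-length rates before, during and after a compartment
#'
#' Rates of interface length change (Delta L / Delta t, micrometers per
#' second; negative = contraction) in the 30 s window before a compartment's
#' initiation, over the compartment's lifetime, and in the 30 s window after
#' its termination. Windows extending beyond the series are clipped and
#' flagged truncated.
#'
#' @param length_um interface length series (um; NA allowed outside existence).
#' @param t_start,t_end compartment association interval in frames.
#' @param frame_interval seconds per frame.
#' @param window_s flanking window in seconds (default 30).
#' @return data.frame with one row per window (`pre`, `during`, `post`):
#'   `rate_um_per_s`, `truncated`.
#' @export
interface_rate_windows <- function(length_um, t_start, t_end,
                                   frame_interval = 1, window_s = 30) {
  N <- length(length_um)
  if (t_start < 1 || t_end > N || t_end < t_start)
    stop_invalid("compartment interval outside the series", "invalid_interval")
  w <- round(window_s / frame_interval)
  rate <- function(a, b) {
    if (b <= a) return(NA_real_)
    (length_um[b] - length_um[a]) / ((b - a) * frame_interval)
  }
  pre_a <- max(1L, t_start - w)
  post_b <- min(N, t_end + w)
  data.frame(
    window = c("pre", "during", "post"),
    rate_um_per_s = c(rate(pre_a, t_start), rate(t_start, t_end),
                      rate(t_end, post_b)),
    truncated = c(pre_a > t_start - w, FALSE, post_b < t_end + w))
}
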