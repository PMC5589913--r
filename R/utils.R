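# Reflective (mirror) index vector for padding-free boundary handling:
# maps positions 1-n shifted by `off` back into 1..n.
reflect_index <- function(n, off) {
  idx <- seq_len(n) + off
  # reflect about the edges (no repeated edge sample), period 2(n-1)
  if (n == 1L) return(rep(1L, n))
  p <- 2L * (n - 1L)
  idx <- ((idx - 1L) %% p + p) %% p
  ifelse(idx >= n, p - idx, idx) + 1L
}

#' One-dimensional Gaussian smoothing with reflected boundaries
#'
#' @param x numeric vector (may contain NA; NAs are interpolated before
#'   filtering and restored after).
#' @param sigma kernel standard deviation in samples; 0 returns `x`.
#' @param truncate kernel half-width in sigmas.
#' @return filtered vector, same length as `x`.
#' @keywords internal
gaussian_filter1d <- function(x, sigma, truncate = 4) {
  if (sigma <= 0) return(x)
  n <- length(x)
  # beyond a few reflection periods the kernel sees only repeats of the
  # same samples; cap the support there (result -> global mean as sigma
  # grows, which is the right limit for a trend filter)
  half <- max(1L, as.integer(min(ceiling(truncate * sigma), 4 * (n - 1L))))
  k <- exp(-0.5 * (seq(-half, half) / sigma)^2)
  k <- k / sum(k)
  na <- is.na(x)
  if (any(na)) {
    if (all(na)) return(x)
    x <- stats::approx(which(!na), x[!na], xout = seq_len(n), rule = 2)$y
  }
  out <- numeric(n)
  acc <- numeric(n)
  for (j in seq_along(k)) {
    acc <- acc + k[j] * x[reflect_index(n, j - half - 1L)]
  }
  acc[na] <- NA_real_
  acc
}

# Analytic signal via FFT; returns complex vector whose modulus is the
# instantaneous amplitude envelope (discrete Hilbert construction).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Separable convolution of a matrix with a 1-D kernel dilated by `step`
# (zeros inserted between taps), reflected boundaries. Used by the
# a-trous transform and by local box statistics.
conv_sep_dilated <- function(img, kernel, step = 1L) {
  half <- (length(kernel) - 1L) %/% 2L
  offs <- (seq_along(kernel) - half - 1L) * step
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (j in seq_along(kernel)) out <- out + kernel[j] * img[reflect_index(nr, offs[j]), , drop = FALSE]
  img <- out
  out <- matrix(0, nr, nc)
  for (j in seq_along(kernel)) out <- out + kernel[j] * img[, reflect_index(nc, offs[j]), drop = FALSE]
  out
}

# Local mean and population variance over a w x w neighborhood
# (reflected borders), via separable box filters.
local_box_stats <- function(img, w = 9L) {
  k <- rep(1 / w, w)
  m <- conv_sep_dilated(img, k)
  m2 <- conv_sep_dilated(img * img, k)
  v <- pmax(m2 - m * m, 0)
  list(mean = m, var = v)
}

# Run-length extraction of TRUE runs: returns data.frame(start, end, length)
true_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

stop_invalid <- function(msg, class) {
  stop(structure(class = c(class, "epiratchet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
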