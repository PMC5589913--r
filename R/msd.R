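#' Mean squared displacement of a trajectory
#'
#' For a scalar length trajectory l sampled every dt seconds,
#' MSD(n dt) = (1 / (N - n)) * sum_k (l[k + n] - l[k])^2, k = 1..N-n.
#' For 2-D position trajectories (an N x 2 matrix) the squared Euclidean
#' displacement is used. All sample pairs at each lag are averaged
#' (time-averaged MSD).
#'
#' @param traj numeric vector (scalar trajectory, micrometers) or N x 2
#'   matrix (2-D positions).
#' @param max_lag largest lag in frames; must be < number of samples.
#' @param frame_interval seconds per frame (used for the `tau_s` column).
#' @return data.frame with columns `lag` (frames), `tau_s`, `msd`, `n_pairs`.
#' @export
compute_msd <- function(traj, max_lag, frame_interval = 1) {
  x <- if (is.matrix(traj)) traj else matrix(traj, ncol = 1)
  N <- nrow(x)
  if (N < 2) stop_invalid("trajectory needs >= 2 samples", "invalid_input")
  if (max_lag >= N || max_lag < 1)
    stop_invalid("max_lag must be in [1, N-1]", "invalid_lag")
  msd <- numeric(max_lag)
  npairs <- integer(max_lag)
  for (n in seq_len(max_lag)) {
    d2 <- rowSums((x[(n + 1):N, , drop = FALSE] - x[1:(N - n), , drop = FALSE])^2)
    msd[n] <- mean(d2)
    npairs[n] <- N - n
  }
  data.frame(lag = seq_len(max_lag), tau_s = seq_len(max_lag) * frame_interval,
             msd = msd, n_pairs = npairs)
}

#' Fit the three-component MSD model
#'
#' Nonnegative-constrained least squares fit of
#' MSD(tau) = A (1 - exp(-alpha tau)) + 2 B tau + C^2 tau^2:
#' a confined component with plateau amplitude A (um^2) and rate alpha (1/s),
#' a diffusive component with coefficient B (um^2/s), and an active
#' (ballistic) component with speed C (um/s). Fitting is Levenberg-Marquardt
#' with box constraints and multi-start initialization. Because the three
#' components alias each other on degenerate inputs (a slowly relaxing
#' confined term is linear over any finite lag range, exactly like
#' diffusion), every subset of components is fitted and components are
#' retained only when they earn their keep: a larger subset replaces a
#' nested smaller one only if it reduces the weighted residual sum of
#' squares by at least `selection_factor` per added parameter. Absent
#' components report 0. Residuals are weighted by the MSD estimator's
#' relative standard error, sqrt(lag / n_pairs), when the curve carries
#' those columns, so the well-estimated short lags anchor the fit.
#'
#' @param curve data.frame as returned by [compute_msd] (columns `tau_s`,
#'   `msd`, optionally `lag`, `n_pairs`); >= 5 lag points required.
#' @param weights `"se"` (default; inverse relative-standard-error weights),
#'   `"relative"` (1/msd), or `"none"`.
#' @param selection_factor required RSS-improvement factor per added
#'   component parameter (default 3; larger = more conservative).
#' @return list of class `msd_fit`: `A`, `alpha`, `B`, `C`, `residual`
#'   (weighted residual sum of squares of the selected model), `model`
#'   (component subset chosen), `fitted`, `tau_s`.
#' @export
fit_msd <- function(curve, weights = c("se", "relative", "none"),
                    selection_factor = 3) {
  weights <- match.arg(weights)
  tau <- curve$tau_s; y <- curve$msd
  if (length(tau) < 5) stop_invalid("need >= 5 lag points", "invalid_input")
  eps <- 1e-12
  w <- switch(weights,
              none = rep(1, length(y)),
              relative = 1 / pmax(y, eps),
              se = if (!is.null(curve$n_pairs) && !is.null(curve$lag))
                sqrt(curve$n_pairs / curve$lag) / pmax(y, eps)
              else 1 / pmax(y, eps))
  model <- function(p, tau) p[1] * (1 - exp(-p[2] * tau)) + 2 * p[3] * tau + p[4]^2 * tau^2
  y_end <- mean(utils::tail(y, max(3, length(y) %/% 10)))
  slope0 <- max((y[min(5, length(y))] - y[1]) / (tau[min(5, length(y))] - tau[1]), 0)
  tmax <- max(tau)

  # component subsets: free parameter indices of c(A, alpha, B, C)
  subsets <- list(B = 3L, C = 4L, conf = c(1L, 2L), BC = c(3L, 4L),
                  confB = c(1L, 2L, 3L), confC = c(1L, 2L, 4L),
                  full = c(1L, 2L, 3L, 4L))
  lower <- c(0, 1e-8, 0, 0)
  base_starts <- list(
    c(max(y_end, eps) / 2, 2 / tmax, slope0 / 2, 0),
    c(max(y_end, eps), 20 / tmax, 0, sqrt(max(y_end, eps)) / tmax),
    c(max(y_end, eps) / 10, 100 / tmax, slope0 / 2, sqrt(max(y_end, eps)) / (2 * tmax)))
  fits <- vector("list", length(subsets))
  names(fits) <- names(subsets)
  for (s in names(subsets)) {
    free <- subsets[[s]]
    sub_best <- NULL
    for (p0 in base_starts) {
      pf <- p0
      pf[setdiff(1:4, free)] <- 0
      pf[2] <- max(pf[2], lower[2])
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = pf[free], lower = lower[free],
          fn = function(pp) {
            p <- numeric(4); p[2] <- 1  # alpha irrelevant when A = 0
            p[free] <- pp
            w * (y - model(p, tau))
          },
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(sub_best) || rss < sub_best$rss)
        sub_best <- list(par = fit$par, rss = rss)
    }
    fits[[s]] <- sub_best
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop_invalid("MSD fit failed to converge from all starts", "fit_failure")
  sizes <- vapply(subsets, length, integer(1))
  rss <- vapply(fits, function(f) if (is.null(f)) Inf else f$rss, numeric(1))
  chosen <- NULL
  for (i in order(sizes, rss)) {
    if (!ok[i]) next
    if (is.null(chosen)) { chosen <- i; next }
    extra <- sizes[i] - sizes[chosen]
    if (extra > 0 && all(subsets[[chosen]] %in% subsets[[i]]) &&
        rss[i] * selection_factor^extra < rss[chosen])
      chosen <- i
  }
  p <- numeric(4)
  p[subsets[[chosen]]] <- fits[[chosen]]$par
  structure(list(A = p[1], alpha = p[2], B = p[3], C = p[4],
                 residual = rss[chosen], model = names(subsets)[chosen],
                 fitted = model(p, tau), tau_s = tau),
            class = "msd_fit")
}

#' Per-trajectory MSD component estimates
#'
#' Convenience wrapper for single-trajectory analysis: computes the MSD to
#' `max_lag` (default a quarter of the trajectory) and fits the
#' three-component model over the first `fit_lags` lags only. The
#' restriction matters for single trajectories: the time-averaged MSD's
#' errors are strongly correlated and grow with lag, so component fits on
#' the full curve chase long-lag wander; short-lag fitting is the standard
#' remedy.
#'
#' @param traj numeric vector or N x 2 matrix.
#' @param frame_interval seconds per frame.
#' @param max_lag MSD extent in frames (default `floor(N/4)`).
#' @param fit_lags number of initial lags used for the component fit
#'   (default `min(60, max_lag)`).
#' @param ... passed to [fit_msd].
#' @return an `msd_fit` whose `curve` element holds the full MSD curve.
#' @export
msd_components <- function(traj, frame_interval = 1, max_lag = NULL,
                           fit_lags = NULL, ...) {
  N <- if (is.matrix(traj)) nrow(traj) else length(traj)
  if (is.null(max_lag)) max_lag <- max(5L, N %/% 4L)
  curve <- compute_msd(traj, max_lag, frame_interval)
  if (is.null(fit_lags)) fit_lags <- min(60L, max_lag)
  fit <- fit_msd(curve[seq_len(fit_lags), ], ...)
  fit$curve <- curve
  fit
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("msd_fit: A=%.4g um^2, alpha=%.4g 1/s, B=%.4g um^2/s, C=%.4g um/s (rss=%.3g)\n",
              x$A, x$alpha, x$B, x$C, x$residual))
  invisible(x)
}
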