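# Filtering, gap interpolation and stream synchronization.

# steady-state initial filter state per unit input level (direct form II
# transposed), so a constant signal passes with no startup transient
lfilter_zi <- function(b, a) {
  N <- length(a) - 1L
  comp <- matrix(0, N, N)
  comp[1, ] <- -a[-1] / a[1]
  if (N > 1) comp[cbind(2:N, 1:(N - 1))] <- 1
  solve(diag(N) - t(comp), b[-1] - a[-1] * b[1])
}

filter_df2t <- function(b, a, x, zi) {
  N <- length(a) - 1L
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (N > 1L) z[1:(N - 1L)] <- b[2:N] * xi + z[2:N] - a[2:N] * yi
    z[N] <- b[N + 1L] * xi - a[N + 1L] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of an n-th order Butterworth low-pass, so the
#' net magnitude response is |H|^2 (amplitude 0.5 at the cutoff for any
#' order) and the phase lag is zero.  The signal is extended by odd
#' reflection over 3 x order samples at each end and the filter state is
#' initialized at steady state, so constants pass exactly and there is no
#' startup transient.
#'
#' @param x numeric vector or matrix (filtered column-wise).
#' @param rate sampling frequency, Hz.
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param order filter order (default 4).
#' @return filtered signal, same shape as `x`.
#' @export
lowpass_zero_phase <- function(x, rate, cutoff, order = 4L) {
  if (cutoff >= rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         rate / 2, " Hz)")
  if (is.matrix(x))
    return(apply(x, 2, lowpass_zero_phase, rate = rate, cutoff = cutoff,
                 order = order))
  n <- length(x)
  if (n <= 3L * order)
    stop("series too short to filter: ", n, " samples for order ", order)
  if (anyNA(x)) stop("cannot filter a signal containing NA; fill gaps first")
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  b <- bf$b; a <- bf$a
  zi <- lfilter_zi(b, a)
  npad <- 3L * order
  # odd (point-symmetric) reflection about the end samples
  head_pad <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xe <- c(head_pad, x, tail_pad)
  y <- filter_df2t(b, a, xe, zi * xe[1])
  y <- rev(y)
  y <- rev(filter_df2t(b, a, y, zi * y[1]))
  y[seq(npad + 1L, npad + n)]
}

#' Interpolate short marker gaps
#'
#' Gaps of at most `max_gap_s` that are bracketed by valid samples are filled
#' with a cubic spline through the marker's valid samples and unflagged;
#' longer gaps and gaps touching the series boundary are left flagged (no
#' extrapolation).
#'
#' @param series a [marker_series()].
#' @param max_gap_s longest gap to interpolate, s.
#' @return a `marker_series` with short interior gaps filled.
#' @export
fill_gaps <- function(series, max_gap_s = 0.2) {
  n <- n_samples(series)
  max_len <- floor(max_gap_s * series$rate)
  pos <- series$positions
  gaps <- series$gaps
  for (lab in series$labels) {
    g <- gaps[, lab]
    if (!any(g)) next
    runs <- rle(g)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    good <- which(!g)
    if (length(good) < 2L) next
    for (k in which(runs$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 == 1L || i1 == n) next              # boundary: no extrapolation
      if (runs$lengths[k] > max_len) next        # too long
      idx <- i0:i1
      for (ax in 1:3) {
        sp <- stats::spline(x = good, y = pos[good, ax, lab],
                            xout = idx, method = "natural")
        pos[idx, ax, lab] <- sp$y
      }
      gaps[idx, lab] <- FALSE
    }
  }
  marker_series(pos, series$labels, series$rate, gaps = gaps)
}

#' Synchronize marker and hand-rim streams onto a common timebase
#'
#' Both streams are assumed to start at their shared hardware trigger (t = 0).
#' Each is resampled in time to `target_rate` by cubic-spline interpolation
#' (accurate enough that a 240-50-240 Hz round trip of a 2 Hz signal stays
#' within 1e-3 of its amplitude) and truncated to the shorter common
#' duration.
#'
#' @param markers a [marker_series()] (gaps must be filled or absent).
#' @param rim a [handrim_series()].
#' @param target_rate common output rate, Hz (default: the rim rate).
#' @return An object of class `aligned_trial` with elements `markers`, `rim`,
#'   `common_rate` and `t` (sample times, s).
#' @export
synchronize <- function(markers, rim, target_rate = rim$rate) {
  if (target_rate > 4 * markers$rate || target_rate > 4 * rim$rate)
    warning("target_rate exceeds 4x a source rate; interpolation only")
  dur <- min((n_samples(markers) - 1L) / markers$rate,
             (n_samples(rim) - 1L) / rim$rate)
  if (dur <= 0) stop("zero-length overlap between streams")
  t_out <- seq(0, dur, by = 1 / target_rate)
  t_mk <- (seq_len(n_samples(markers)) - 1L) / markers$rate
  t_rm <- (seq_len(n_samples(rim)) - 1L) / rim$rate
  res <- function(t_in, y) stats::spline(t_in, y, xout = t_out,
                                         method = "fmm")$y
  n <- length(t_out)
  pos <- array(NA_real_, c(n, 3, length(markers$labels)),
               dimnames = list(NULL, c("x", "y", "z"), markers$labels))
  for (lab in markers$labels)
    for (ax in 1:3)
      pos[, ax, lab] <- res(t_mk, markers$positions[, ax, lab])
  mk <- marker_series(pos, markers$labels, target_rate)
  rm_ <- handrim_series(
    F = cbind(res(t_rm, rim$F[, 1]), res(t_rm, rim$F[, 2]),
              res(t_rm, rim$F[, 3])),
    M = cbind(res(t_rm, rim$M[, 1]), res(t_rm, rim$M[, 2]),
              res(t_rm, rim$M[, 3])),
    theta = res(t_rm, rim$theta), rate = target_rate, side = rim$side)
  structure(list(markers = mk, rim = rm_, common_rate = target_rate,
                 t = t_out),
            class = "aligned_trial")
}

#' @export
print.aligned_trial <- function(x, ...) {
  cat(sprintf("aligned_trial: %d samples @ %g Hz (%.2f s)\n",
              length(x$t), x$common_rate, max(x$t)))
  invisible(x)
}
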