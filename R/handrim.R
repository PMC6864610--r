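# Hand-rim kinetic variables over the push phase: total, tangential and
# effective force, elevation rates, total moment, and per-instant values.

#' Total hand-rim force
#'
#' Pointwise Euclidean norm of the measured rim force vector.
#'
#' @param F `[n, 3]` force matrix, N.
#' @return numeric vector of |F|, N.
#' @export
total_force <- function(F) {
  F <- rbind(F)
  sqrt(rowSums(F^2))
}

#' Tangential hand-rim force
#'
#' Ftang = -Fx sin(theta) + Fy cos(theta): the component of the rim force in
#' the direction of forward rotation at wheel angle theta.
#'
#' @param F `[n, 3]` force matrix, N.
#' @param theta wheel angle, rad, same length as `F` rows.
#' @return numeric vector, N (positive = propulsive).
#' @export
tangential_force <- function(F, theta) {
  F <- rbind(F)
  if (nrow(F) != length(theta)) stop("F and theta length mismatch")
  -F[, 1] * sin(theta) + F[, 2] * cos(theta)
}

#' Effective force fraction over a push
#'
#' Mean over the push phase of the pointwise ratio Ftang / Ftot.  Samples
#' with Ftot below `min_force` are excluded to keep the ratio numerically
#' stable at the push edges.
#'
#' @param F `[n, 3]` force matrix, N.
#' @param theta wheel angle, rad.
#' @param push integer index range of the push phase.
#' @param min_force exclusion threshold on Ftot, N (default 1).
#' @return dimensionless scalar in `[-1, 1]`.
#' @export
effective_force <- function(F, theta, push, min_force = 1) {
  if (!length(push)) stop("empty push range")
  ftot <- total_force(F[push, , drop = FALSE])
  ftan <- tangential_force(F[push, , drop = FALSE], theta[push])
  keep <- ftot >= min_force
  if (!any(keep)) stop("all push samples below ", min_force, " N")
  mean(ftan[keep] / ftot[keep])
}

#' Elevation rate of a force or moment signal
#'
#' Maximum central-difference derivative over the loading portion of the
#' push: from hand-on up to the in-push peak of the signal.
#'
#' @param x scalar signal (e.g. total force), over the full recording.
#' @param rate sampling frequency, Hz.
#' @param push integer index range of the push phase.
#' @return peak rate of rise, units of `x` per second.
#' @export
elevation_rate <- function(x, rate, push) {
  if (length(push) < 3L) stop("push range must contain at least 3 samples")
  xi <- x[push]
  i_peak <- which.max(xi)
  if (i_peak < 2L) return(0)
  d <- central_diff(xi, 1 / rate)
  max(d[seq_len(i_peak)])
}

central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  d <- numeric(n)
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

#' Summarize hand-rim kinetics over one propulsion cycle
#'
#' Maxima of total force, tangential force and total moment over the push
#' phase, effective force fraction, elevation rates of total force (ERF) and
#' total moment (ERM), and force/moment values at the propulsion instants.
#'
#' @param rim a [handrim_series()].
#' @param cycle a `propulsion_cycle` (instants located where available).
#' @return An object of class `handrim_summary`.
#' @export
summarize_handrim <- function(rim, cycle) {
  n <- n_samples(rim)
  if (cycle$i_end > n) stop("cycle indices exceed series length")
  push <- cycle$i_HO:cycle$i_HR
  ftot <- total_force(rim$F)
  ftan <- tangential_force(rim$F, rim$theta)
  mtot <- sqrt(rowSums(rim$M^2))
  if (max(ftot[push]) < 1) stop("no push: total force below 1 N throughout")
  instants <- c(HO = cycle$i_HO, TC = cycle$i_TC, HR = cycle$i_HR,
                FT = cycle$i_FT, AR = cycle$i_AR)
  at_inst <- function(x) vapply(instants, function(i)
    if (is.na(i)) NA_real_ else x[i], numeric(1))
  structure(list(
    Ftot_max = max(ftot[push]),
    Ftang_max = max(ftan[push]),
    Feff = effective_force(rim$F, rim$theta, push),
    ERF = elevation_rate(ftot, rim$rate, push),
    Mtot_max = max(mtot[push]),
    ERM = elevation_rate(mtot, rim$rate, push),
    Ftot_at = at_inst(ftot), Ftang_at = at_inst(ftan),
    Mtot_at = at_inst(mtot)),
    class = "handrim_summary")
}

#' @export
print.handrim_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "handrim_summary:\n",
    "  Ftot_max  %7.2f N    Ftang_max %7.2f N   Feff %5.3f\n",
    "  ERF     %9.1f N/s  Mtot_max  %7.2f Nm  ERM %8.1f Nm/s\n"),
    x$Ftot_max, x$Ftang_max, x$Feff, x$ERF, x$Mtot_max, x$ERM))
  invisible(x)
}

#' Average hand-rim summaries over cycles
#'
#' Per-cycle summaries are computed and their scalar fields averaged, the
#' aggregation used for reporting.
#'
#' @param rim a [handrim_series()].
#' @param cycles list of `propulsion_cycle`s.
#' @return `handrim_summary` of cycle means.
#' @export
summarize_handrim_cycles <- function(rim, cycles) {
  per <- lapply(cycles, function(cy) summarize_handrim(rim, cy))
  agg <- function(field) mean(vapply(per, `[[`, numeric(1), field))
  agg_v <- function(field) {
    m <- do.call(rbind, lapply(per, `[[`, field))
    colMeans(m)
  }
  structure(list(
    Ftot_max = agg("Ftot_max"), Ftang_max = agg("Ftang_max"),
    Feff = agg("Feff"), ERF = agg("ERF"),
    Mtot_max = agg("Mtot_max"), ERM = agg("ERM"),
    Ftot_at = agg_v("Ftot_at"), Ftang_at = agg_v("Ftang_at"),
    Mtot_at = agg_v("Mtot_at")),
    class = "handrim_summary")
}
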