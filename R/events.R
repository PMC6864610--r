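# Push/release detection, cycle segmentation, propulsion instants,
# time-normalization and temporal-spatial variables.
#
# Propulsion instants: HO (hand on), TC (top centre), HR (hand release),
# FT (follow-through, most anterior hand position), AR (arm preparation,
# most posterior hand position).

#' Detect push phases from the axle moment
#'
#' A push starts when the propulsion moment rises above `threshold` and ends
#' when it falls back below it.  A trailing push with no release before the
#' end of the series is discarded, as are pushes shorter than `min_push_s`
#' (debounce against threshold chatter).
#'
#' @param rim_moment axle propulsion moment (typically filtered M_z), Nm.
#' @param threshold detection threshold, Nm (default 1).
#' @param rate sampling frequency, Hz.
#' @param min_push_s minimum push duration, s (default 0.1).
#' @return integer matrix with columns `i_on`, `i_off` (one row per push);
#'   zero rows if none.
#' @export
detect_pushes <- function(rim_moment, threshold = 1, rate,
                          min_push_s = 0.1) {
  if (threshold <= 0) stop("threshold must be > 0")
  n <- length(rim_moment)
  above <- rim_moment > threshold
  on <- which(above & !c(TRUE, above[-n]))     # rising crossings (never i=1)
  off <- which(!above & c(FALSE, above[-n]))   # falling crossings
  keep_on <- integer(0); keep_off <- integer(0)
  j <- 1L
  for (i in on) {
    while (j <= length(off) && off[j] <= i) j <- j + 1L
    if (j > length(off)) break                  # incomplete trailing push
    keep_on <- c(keep_on, i); keep_off <- c(keep_off, off[j])
    j <- j + 1L
  }
  keep <- (keep_off - keep_on) / rate >= min_push_s
  cbind(i_on = keep_on[keep], i_off = keep_off[keep])
}

#' Segment propulsion cycles from detected pushes
#'
#' One cycle per consecutive push pair, spanning hand-on to the next hand-on.
#' The last push starts no cycle.
#'
#' @param pushes matrix from [detect_pushes()].
#' @param rate sampling frequency, Hz.
#' @return list of `propulsion_cycle` objects (empty if fewer than 2 pushes).
#' @export
segment_cycles <- function(pushes, rate) {
  if (is.null(pushes) || nrow(pushes) < 2L) return(list())
  lapply(seq_len(nrow(pushes) - 1L), function(k) {
    i_HO <- as.integer(pushes[k, "i_on"])
    i_HR <- as.integer(pushes[k, "i_off"])
    i_end <- as.integer(pushes[k + 1L, "i_on"])
    structure(list(i_HO = i_HO, i_HR = i_HR, i_end = i_end,
                   i_TC = NA_integer_, i_FT = NA_integer_,
                   i_AR = NA_integer_,
                   Pphase = (i_HR - i_HO) / rate,
                   Rphase = (i_end - i_HR) / rate,
                   rate = rate),
              class = "propulsion_cycle")
  })
}

#' @export
print.propulsion_cycle <- function(x, ...) {
  cat(sprintf(
    "propulsion_cycle: HO=%d HR=%d end=%d  push %.3f s, recovery %.3f s\n",
    x$i_HO, x$i_HR, x$i_end, x$Pphase, x$Rphase))
  invisible(x)
}

#' Select consecutive cycles inside an analysis window
#'
#' @param cycles list from [segment_cycles()].
#' @param window `c(start_s, end_s)` analysis window.
#' @param n number of consecutive cycles required.
#' @return the first `n` consecutive cycles fully inside the window.
#' @export
select_cycles <- function(cycles, window = c(0, Inf), n = 5L) {
  if (n < 1) stop("n must be >= 1")
  inside <- vapply(cycles, function(cy) {
    t0 <- (cy$i_HO - 1L) / cy$rate; t1 <- (cy$i_end - 1L) / cy$rate
    t0 >= window[1] && t1 <= window[2]
  }, logical(1))
  idx <- which(inside)
  if (length(idx) < n)
    stop("insufficient cycles in window: need ", n, ", found ", length(idx))
  cycles[idx[seq_len(n)]]
}

#' Angular rim position of a lab-frame point
#'
#' The angle is measured in the wheel plane from the backward horizontal,
#' increasing in the direction of forward rotation (top centre = 90 degrees).
#'
#' @param p lab point(s): 3-vector or `[n, 3]` matrix.
#' @param geometry a [wheelchair_geometry()].
#' @return angle(s) in radians in `[0, 2*pi)`.
#' @export
rim_angle_of_point <- function(p, geometry) {
  p <- rbind(p)
  ax <- geometry$axle_position
  a <- atan2(p[, 3] - ax[3], -(p[, 1] - ax[1]))
  a %% (2 * pi)
}

#' Locate the propulsion instants within a cycle
#'
#' TC is the push-phase sample whose rim angle is closest to top centre;
#' FT/AR are the most anterior / most posterior hand positions over the whole
#' cycle (ties broken by the earliest index).
#'
#' @param cycle a `propulsion_cycle`.
#' @param hand_xyz `[n, 3]` trajectory of the hand marker (third metacarpus).
#' @param geometry a [wheelchair_geometry()].
#' @param contact_xyz optional `[n, 3]` trajectory of the grip point used for
#'   the top-centre angle (default: `hand_xyz`; the analysis pipeline passes
#'   the wrist centre).
#' @return the cycle with `i_TC`, `i_FT`, `i_AR` filled in.
#' @export
locate_instants <- function(cycle, hand_xyz, geometry,
                            contact_xyz = hand_xyz) {
  if (cycle$i_end > nrow(hand_xyz)) stop("cycle indices exceed series length")
  push <- cycle$i_HO:cycle$i_HR
  ang <- rim_angle_of_point(contact_xyz[push, , drop = FALSE], geometry)
  cycle$i_TC <- push[which.min(abs(ang - pi / 2))]
  span <- cycle$i_HO:cycle$i_end
  x <- hand_xyz[span, 1]
  cycle$i_FT <- span[which.max(x)]
  cycle$i_AR <- span[which.min(x)]
  cycle
}

#' Time-normalize a signal over one propulsion cycle
#'
#' Linear interpolation of the hand-on to next-hand-on span onto `n_points`
#' equally spaced stations (0-100% cycle); endpoint samples are preserved
#' exactly.
#'
#' @param x numeric vector or `[n, k]` matrix over the full recording.
#' @param cycle a `propulsion_cycle`.
#' @param n_points number of stations (default 101).
#' @return vector (or matrix) of length `n_points`.
#' @export
normalize_cycle <- function(x, cycle, n_points = 101L) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (cycle$i_end - cycle$i_HO < 1L) stop("cycle shorter than 2 samples")
  stations <- seq(cycle$i_HO, cycle$i_end, length.out = n_points)
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col)
      stats::approx(seq_along(col), col, xout = stations)$y)
    return(out)
  }
  stats::approx(seq_along(x), x, xout = stations)$y
}

#' Temporal-spatial propulsion variables
#'
#' Cadence PF (strokes/s), mean push and recovery phase durations and their
#' ratio, distance covered per cycle (wheel radius times wheel rotation), and
#' contact/release angles CA/RA in degrees from the backward horizontal.
#' CA/RA are taken from the hand position projected onto the wheel circle
#' when a hand trajectory is supplied, otherwise from the wheel angle stream
#' modulo one turn (which then requires a declared encoder zero).
#'
#' @param cycles list of selected `propulsion_cycle`s.
#' @param rim a [handrim_series()] on the same timebase.
#' @param geometry a [wheelchair_geometry()].
#' @param hand_xyz optional `[n, 3]` hand-marker trajectory for CA/RA.
#' @return An object of class `temporal_spatial` (a named list).
#' @export
temporal_spatial <- function(cycles, rim, geometry, hand_xyz = NULL) {
  if (!length(cycles)) stop("empty cycle list")
  rate <- cycles[[1]]$rate
  total_s <- (cycles[[length(cycles)]]$i_end - cycles[[1]]$i_HO) / rate
  Pp <- vapply(cycles, `[[`, numeric(1), "Pphase")
  Rp <- vapply(cycles, `[[`, numeric(1), "Rphase")
  dtheta <- vapply(cycles, function(cy)
    rim$theta[cy$i_end] - rim$theta[cy$i_HO], numeric(1))
  r_wheel <- geometry$wheel_diameter / 2
  ang_at <- function(i) {
    if (!is.null(hand_xyz))
      rim_angle_of_point(hand_xyz[i, ], geometry) * 180 / pi
    else (rim$theta[i] %% (2 * pi)) * 180 / pi
  }
  CA <- vapply(cycles, function(cy) ang_at(cy$i_HO), numeric(1))
  RA <- vapply(cycles, function(cy) ang_at(cy$i_HR), numeric(1))
  structure(list(
    PF = length(cycles) / total_s,
    Pphase = mean(Pp), Rphase = mean(Rp),
    ratio = mean(Pp) / mean(Rp),
    ratio_per_cycle = Pp / Rp,
    Dist = r_wheel * mean(dtheta),
    CA = mean(CA), RA = mean(RA),
    n_cycles = length(cycles)),
    class = "temporal_spatial")
}

#' @export
print.temporal_spatial <- function(x, ...) {
  cat(sprintf(paste0(
    "temporal_spatial (%d cycles):\n",
    "  PF    %.3f st/s\n  Dist  %.3f m\n",
    "  Pphase %.3f s  Rphase %.3f s  ratio %.3f\n",
    "  CA %.1f deg  RA %.1f deg\n"),
    x$n_cycles, x$PF, x$Dist, x$Pphase, x$Rphase, x$ratio, x$CA, x$RA))
  invisible(x)
}
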