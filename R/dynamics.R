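# Newton-Euler inverse dynamics from the measured hand-rim load to the
# glenohumeral joint.
#
# Joint loads are reported as the action of the proximal segment on the
# distal one, expressed in lab axes, whose components carry the usual
# anatomical meaning for a forward-facing subject: Fx +anterior/-posterior,
# Fy +lateral/-medial (left positive), Fz +superior/-inferior; Mx
# +adduction/-abduction (+cubital/-radial at the wrist), My
# +flexion/-extension, Mz +pronation/-supination (+internal/-external
# rotation at shoulder and wrist).

#' Lab-frame hand-rim load
#'
#' Decodes the sensor stream into lab-frame force and moment.  The stored
#' components are defined so that evaluating the tangential/radial formulas
#' at the recorded wheel angle yields the physical tangential and radial
#' components; those are mapped into the lab frame at the hand's angular rim
#' position.
#'
#' @param rim a [handrim_series()].
#' @param hand_angle angular rim position of the hand per sample, rad
#'   (from [rim_angle_of_point()]).
#' @param geometry a [wheelchair_geometry()].
#' @return list with `F_lab` (`[n, 3]`, hand-on-rim force, N), `M_lab`
#'   (`[n, 3]`, moment about the hub, Nm) and `contact` (`[n, 3]`, lab
#'   contact points, m).
#' @export
rim_load_lab <- function(rim, hand_angle, geometry) {
  th <- rim$theta
  f_tan <- tangential_force(rim$F, th)
  f_rad <- rim$F[, 1] * cos(th) + rim$F[, 2] * sin(th)
  f_ax <- rim$F[, 3]
  ax <- geometry$axle_position
  # sensor basis in lab axes: X backward, Y up, Z inboard (right wheel)
  r_hat <- cbind(-cos(hand_angle), 0, sin(hand_angle))
  t_hat <- cbind(sin(hand_angle), 0, cos(hand_angle))
  F_lab <- f_rad * r_hat + f_tan * t_hat + cbind(0, f_ax, 0)
  dimnames(F_lab) <- NULL
  M_lab <- cbind(-rim$M[, 1], rim$M[, 3], rim$M[, 2])
  contact <- cbind(ax[1] - geometry$rim_radius * cos(hand_angle),
                   ax[2],
                   ax[3] + geometry$rim_radius * sin(hand_angle))
  list(F_lab = F_lab, M_lab = M_lab, contact = contact)
}

rows_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Inverse dynamics of the upper limb
#'
#' Newton-Euler recursion hand -> wrist -> elbow -> glenohumeral joint.  The
#' external load on the hand is the reaction of the measured rim load,
#' applied at the hand's projection onto the rim circle; any part of the
#' measured hub moment not explained by the contact force is carried as a
#' couple.
#'
#' @param frames a [build_frames()] result (same timebase as `rim`).
#' @param motion a [derive_motion()] result.
#' @param inertia a [segment_inertia()] result.
#' @param rim a [handrim_series()] on the same timebase.
#' @param geometry a [wheelchair_geometry()].
#' @return An object of class `joint_kinetics`: per joint (`wrist`, `elbow`,
#'   `shoulder`) matrices `F` and `M` (`[n, 3]`, lab axes).
#' @export
inverse_dynamics <- function(frames, motion, inertia, rim, geometry) {
  n <- frames$n
  if (n_samples(rim) != n)
    stop("rim series and frames have different lengths; synchronize first")
  wc <- frames$hand$origin
  hand_angle <- rim_angle_of_point(wc, geometry)
  load <- rim_load_lab(rim, hand_angle, geometry)
  ax <- geometry$axle_position
  # reaction on the hand; couple = unexplained part of the hub moment
  F_ext <- -load$F_lab
  arm_c <- load$contact - matrix(ax, n, 3, byrow = TRUE)
  M_couple <- -(load$M_lab - rows_cross(arm_c, load$F_lab))
  joints <- list(
    hand = list(p_prox = frames$hand$origin, seg = "hand"),
    forearm = list(p_prox = frames$forearm$origin, seg = "forearm"),
    arm = list(p_prox = frames$arm$origin, seg = "arm"))
  F_dist <- F_ext; M_dist <- M_couple; p_dist <- load$contact
  out <- list()
  jn <- c(hand = "wrist", forearm = "elbow", arm = "shoulder")
  for (seg in c("hand", "forearm", "arm")) {
    m <- inertia[[seg]]$mass
    mo <- motion[[seg]]
    Iw <- matrix(NA_real_, n, 3); Ia <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      R <- frames[[seg]]$R[, , i]
      I_lab <- R %*% inertia[[seg]]$I_local %*% t(R)
      Iw[i, ] <- I_lab %*% mo$omega[i, ]
      Ia[i, ] <- I_lab %*% mo$alpha[i, ]
    }
    p_prox <- joints[[seg]]$p_prox
    Fj <- m * mo$a_com - matrix(m * GRAVITY, n, 3, byrow = TRUE) - F_dist
    Mj <- Ia + rows_cross(mo$omega, Iw) - M_dist -
      rows_cross(p_dist - mo$com, F_dist) -
      rows_cross(p_prox - mo$com, Fj)
    out[[jn[[seg]]]] <- list(F = Fj, M = Mj)
    F_dist <- -Fj; M_dist <- -Mj; p_dist <- p_prox
  }
  structure(c(out, list(rate = frames$rate)), class = "joint_kinetics")
}

#' @export
print.joint_kinetics <- function(x, ...) {
  for (j in c("wrist", "elbow", "shoulder"))
    cat(sprintf("%-9s |F| peak %7.2f N   |M| peak %7.3f Nm\n", j,
                max(sqrt(rowSums(x[[j]]$F^2))),
                max(sqrt(rowSums(x[[j]]$M^2)))))
  invisible(x)
}
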