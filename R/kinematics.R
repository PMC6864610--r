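# Rigid marker-cluster calibration/reconstruction, ISB-style segment frames,
# Euler joint kinematics and segment motion derivatives.
#
# Lab frame: x forward (travel direction), y to the left, z up.  Segment
# frames (right upper limb): y longitudinal pointing proximally, z lateral
# (to the subject's right), x anterior; columns of each rotation matrix are
# the segment axes expressed in the lab frame.

rot_x <- function(t) {
  c_ <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
rot_y <- function(t) {
  c_ <- cos(t); s <- sin(t)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
rot_z <- function(t) {
  c_ <- cos(t); s <- sin(t)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length axis vector")
  v / n
}

#' Compose an intrinsic Y-X'-Y'' rotation (shoulder sequence)
#' @param a1 first rotation about Y (plane of elevation), rad.
#' @param a2 second rotation about the rotated X (elevation), rad.
#' @param a3 third rotation about the twice-rotated Y (axial rotation), rad.
#' @return 3x3 rotation matrix.
#' @export
euler_yxy <- function(a1, a2, a3) rot_y(a1) %*% rot_x(a2) %*% rot_y(a3)

#' Decompose a rotation as intrinsic Y-X'-Y'' angles
#' @param R 3x3 rotation matrix.
#' @return numeric `c(a1, a2, a3)` in radians; `a2` in `[0, pi]`.
#' @export
euler_yxy_angles <- function(R) {
  a2 <- acos(max(-1, min(1, R[2, 2])))
  if (abs(sin(a2)) < 1e-12)
    return(c(atan2(R[3, 1], R[1, 1]) * sign(R[2, 2]), a2, 0))
  a1 <- atan2(R[1, 2], R[3, 2])
  a3 <- atan2(R[2, 1], -R[2, 3])
  c(a1, a2, a3)
}

#' Compose an intrinsic Z-X'-Y'' rotation (elbow/wrist sequence)
#' @param a1 first rotation about Z (flexion-extension), rad.
#' @param a2 second rotation about the rotated X (deviation/carrying), rad.
#' @param a3 third rotation about the twice-rotated Y (axial rotation), rad.
#' @return 3x3 rotation matrix.
#' @export
euler_zxy <- function(a1, a2, a3) rot_z(a1) %*% rot_x(a2) %*% rot_y(a3)

#' Decompose a rotation as intrinsic Z-X'-Y'' angles
#' @param R 3x3 rotation matrix.
#' @return numeric `c(a1, a2, a3)` in radians; `a2` in `[-pi/2, pi/2]`.
#' @export
euler_zxy_angles <- function(R) {
  a2 <- asin(max(-1, min(1, R[3, 2])))
  if (abs(cos(a2)) < 1e-12)
    return(c(atan2(R[2, 1], R[1, 1]), a2, 0))
  a1 <- atan2(-R[1, 2], R[2, 2])
  a3 <- atan2(-R[3, 1], R[3, 3])
  c(a1, a2, a3)
}

# -- marker clusters ---------------------------------------------------------

cluster_basis <- function(P) {
  # P: 3 x 3 matrix of rows = first three reference markers
  v1 <- P[2, ] - P[1, ]
  v2 <- P[3, ] - P[1, ]
  a <- cross3(v1, v2)
  if (sqrt(sum(a^2)) / 2 < 1e-6)
    stop("collinear reference markers (triangle area below 1e-6 m^2)")
  e1 <- unit3(v1)
  e3 <- unit3(a)
  e2 <- cross3(e3, e1)
  cbind(e1, e2, e3)
}

#' Calibrate rigid marker-cluster templates from a static trial
#'
#' For each cluster, the dependent markers are expressed in a local frame
#' built from the reference markers and averaged over the static frames.
#' Default clusters mirror the reduced 15-marker model: the epicondyles are
#' referenced to the arm cluster (rm1-rm3) and the 2nd/5th metacarpals to the
#' hand reference markers (ulr, rdl, 3m).
#'
#' @param static a [marker_series()] with all cluster markers visible.
#' @param clusters list of lists with elements `reference` (>= 3 labels) and
#'   `dependent` (labels).
#' @return list of `cluster_template` objects.
#' @export
calibrate_cluster <- function(static,
                              clusters = list(
                                arm  = list(reference = c("rm1", "rm2", "rm3"),
                                            dependent = c("epc", "ipc")),
                                hand = list(reference = c("ulr", "rdl", "3m"),
                                            dependent = c("2m", "5m")))) {
  lapply(clusters, function(cl) {
    refs <- cl$reference; deps <- cl$dependent
    if (length(refs) < 3L) stop("cluster needs >= 3 reference markers")
    n <- n_samples(static)
    ref_loc <- 0; dep_loc <- 0
    for (i in seq_len(n)) {
      P <- t(vapply(refs, function(l) static$positions[i, , l], numeric(3)))
      D <- t(vapply(deps, function(l) static$positions[i, , l], numeric(3)))
      if (anyNA(P) || anyNA(D)) stop("gap in static calibration frames")
      B <- cluster_basis(P[1:3, , drop = FALSE])
      ctr <- colMeans(P)
      ref_loc <- ref_loc + sweep(P, 2, ctr) %*% B
      dep_loc <- dep_loc + sweep(D, 2, ctr) %*% B
    }
    structure(list(reference = refs, dependent = deps,
                   ref_local = ref_loc / n, dep_local = dep_loc / n),
              class = "cluster_template")
  })
}

kabsch <- function(A, B) {
  # rigid transform mapping rows of A onto rows of B (least squares)
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

#' Reconstruct dependent markers from their cluster templates
#'
#' Each frame's reference markers are registered to the template by the
#' least-squares rigid transform (orthogonal Procrustes) and the transform is
#' applied to the stored dependent-marker coordinates.  Frames with fewer
#' than three visible reference markers leave the dependents gap-flagged.
#'
#' @param templates list from [calibrate_cluster()].
#' @param dynamic a [marker_series()] containing the reference markers.
#' @return a `marker_series` with dependent markers replaced/filled.
#' @export
reconstruct_markers <- function(templates, dynamic) {
  pos <- dynamic$positions
  gaps <- dynamic$gaps
  n <- n_samples(dynamic)
  labs <- dimnames(pos)[[3]]
  for (tpl in templates) {
    for (d in tpl$dependent)
      if (!d %in% labs) stop("dependent marker absent from series: ", d)
    for (i in seq_len(n)) {
      vis <- tpl$reference[!gaps[i, tpl$reference]]
      if (length(vis) < 3L) {
        gaps[i, tpl$dependent] <- TRUE
        pos[i, , tpl$dependent] <- NA_real_
        next
      }
      obs <- t(vapply(vis, function(l) pos[i, , l], numeric(3)))
      loc <- tpl$ref_local[match(vis, tpl$reference), , drop = FALSE]
      tr <- kabsch(loc, obs)
      rec <- sweep(tpl$dep_local %*% t(tr$R), 2, tr$t, `+`)
      for (k in seq_along(tpl$dependent))
        pos[i, , tpl$dependent[k]] <- rec[k, ]
      gaps[i, tpl$dependent] <- FALSE
    }
  }
  marker_series(pos, dynamic$labels, dynamic$rate, gaps = gaps)
}

# -- segment frames ----------------------------------------------------------

frame_from_axes <- function(y_axis, z_raw, segment) {
  y <- tryCatch(unit3(y_axis), error = function(e)
    stop("degenerate ", segment, " frame: zero longitudinal axis"))
  x <- cross3(y, z_raw)
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("degenerate ", segment, " frame: collinear axes")
  x <- x / nx
  z <- cross3(x, y)
  cbind(x, y, z)
}

#' Build trunk, arm, forearm and hand segment frames from markers
#'
#' Trunk from c7 and the acromia; arm from the glenohumeral centre (midpoint
#' of the humeral-head markers) and the epicondyles; forearm from the elbow
#' centre (midpoint epc-ipc) to the wrist centre (midpoint ulr-rdl); hand
#' from the wrist centre, the styloids and the third metacarpal.  All frames
#' are orthonormal right-handed by construction.
#'
#' @param markers a gap-free [marker_series()] with all 15 model markers.
#' @return An object of class `segment_frames`: per segment a list with
#'   `R` (`[3, 3, n]`) and `origin` (`[n, 3]`), plus the sampling `rate`.
#' @export
build_frames <- function(markers) {
  need <- c("c7", "acrr", "acrl", "hha", "hhp", "epc", "ipc",
            "ulr", "rdl", "3m")
  miss <- setdiff(need, markers$labels)
  if (length(miss)) stop("missing markers: ", paste(miss, collapse = ", "))
  if (any(markers$gaps[, need]))
    stop("gaps present in frame-defining markers; fill or reconstruct first")
  n <- n_samples(markers)
  g <- function(l) markers$positions[, , l, drop = TRUE]
  c7 <- rbind(g("c7")); acrr <- rbind(g("acrr")); acrl <- rbind(g("acrl"))
  gh <- (rbind(g("hha")) + rbind(g("hhp"))) / 2
  ec <- (rbind(g("epc")) + rbind(g("ipc"))) / 2
  wc <- (rbind(g("ulr")) + rbind(g("rdl"))) / 2
  m3 <- rbind(g("3m"))
  out <- list(trunk = list(R = array(NA_real_, c(3, 3, n)),
                           origin = matrix(NA_real_, n, 3)),
              arm = list(R = array(NA_real_, c(3, 3, n)), origin = gh),
              forearm = list(R = array(NA_real_, c(3, 3, n)), origin = ec),
              hand = list(R = array(NA_real_, c(3, 3, n)), origin = wc))
  for (i in seq_len(n)) {
    z_t <- acrr[i, ] - acrl[i, ]
    mid <- (acrr[i, ] + acrl[i, ]) / 2
    fwd <- mid - c7[i, ]
    zt <- unit3(z_t)
    xt <- fwd - sum(fwd * zt) * zt
    nx <- sqrt(sum(xt^2))
    if (nx < 1e-9) stop("degenerate trunk frame: collinear defining points")
    xt <- xt / nx
    out$trunk$R[, , i] <- cbind(xt, cross3(zt, xt), zt)
    out$trunk$origin[i, ] <- mid
    out$arm$R[, , i] <- frame_from_axes(gh[i, ] - ec[i, ],
                                        g("epc")[i, ] - g("ipc")[i, ], "arm")
    out$forearm$R[, , i] <- frame_from_axes(ec[i, ] - wc[i, ],
                                            g("rdl")[i, ] - g("ulr")[i, ],
                                            "forearm")
    out$hand$R[, , i] <- frame_from_axes(wc[i, ] - m3[i, ],
                                         g("rdl")[i, ] - g("ulr")[i, ],
                                         "hand")
  }
  structure(c(out, list(rate = markers$rate, n = n)),
            class = "segment_frames")
}

#' @export
print.segment_frames <- function(x, ...) {
  cat(sprintf("segment_frames: trunk/arm/forearm/hand, %d samples @ %g Hz\n",
              x$n, x$rate))
  invisible(x)
}

unwrap_deg <- function(a) unwrap_angle(a * pi / 180) * 180 / pi

interp_flagged <- function(a, flagged) {
  if (!any(flagged) || all(flagged)) return(a)
  idx <- seq_along(a)
  a[flagged] <- stats::approx(idx[!flagged], a[!flagged], xout = idx[flagged],
                              rule = 2)$y
  a
}

#' Euler joint angles of the upper limb
#'
#' Relative distal-in-proximal rotations decomposed with the conventional
#' sequences: shoulder Y-X'-Y'' (plane of elevation, elevation, axial
#' rotation), elbow and wrist Z-X'-Y'' (flexion-extension, deviation/carrying
#' angle, axial rotation = pronation-supination).  Angles are reported in
#' degrees, continuity-unwrapped over time; samples within 1 degree of the
#' sequence singularity are flagged and linearly interpolated.
#'
#' @param frames a [build_frames()] result.
#' @return An object of class `joint_angles_series`: matrix `angles`
#'   (`n x 8`, columns `sh_plane`, `sh_elev`, `sh_rot`, `e_flex`, `e_carry`,
#'   `e_prosup`, `wr_flex`, `wr_dev`, `wr_rot`), logical `gimbal` flags and
#'   the sampling `rate`.
#' @export
joint_angles <- function(frames) {
  n <- frames$n
  ang <- matrix(NA_real_, n, 9)
  colnames(ang) <- c("sh_plane", "sh_elev", "sh_rot",
                     "e_flex", "e_carry", "e_prosup",
                     "wr_flex", "wr_dev", "wr_rot")
  gimbal <- matrix(FALSE, n, 3)
  colnames(gimbal) <- c("shoulder", "elbow", "wrist")
  for (i in seq_len(n)) {
    Rt <- frames$trunk$R[, , i]; Ra <- frames$arm$R[, , i]
    Rf <- frames$forearm$R[, , i]; Rh <- frames$hand$R[, , i]
    sh <- euler_yxy_angles(t(Rt) %*% Ra)
    el <- euler_zxy_angles(t(Ra) %*% Rf)
    wr <- euler_zxy_angles(t(Rf) %*% Rh)
    ang[i, 1:3] <- c(sh[1], sh[2], sh[3])
    ang[i, 4:6] <- c(el[1], el[2], el[3])
    ang[i, 7:9] <- c(wr[1], wr[2], wr[3])
    gimbal[i, 1] <- min(sh[2], pi - sh[2]) < pi / 180
    gimbal[i, 2] <- (pi / 2 - abs(el[2])) < pi / 180
    gimbal[i, 3] <- (pi / 2 - abs(wr[2])) < pi / 180
  }
  ang <- ang * 180 / pi
  joint_of_col <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  for (k in seq_len(ncol(ang))) {
    fl <- gimbal[, joint_of_col[k]]
    ang[, k] <- interp_flagged(ang[, k], fl)
    ang[, k] <- unwrap_deg(ang[, k])
  }
  structure(list(angles = ang, gimbal = gimbal, rate = frames$rate),
            class = "joint_angles_series")
}

#' @export
print.joint_angles_series <- function(x, ...) {
  cat(sprintf("joint_angles_series: %d samples, %d gimbal-flagged\n",
              nrow(x$angles), sum(x$gimbal)))
  invisible(x)
}

# -- segment motion ----------------------------------------------------------

diff_series <- function(x, dt) {
  # central differences on rows of a matrix, one-sided at the endpoints
  n <- nrow(x)
  d <- x * 0
  if (n >= 3)
    d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] -
                       x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}

#' Segment linear and angular kinematics by numerical differentiation
#'
#' Centre-of-mass positions are placed along each segment's longitudinal span
#' at the inertial COM fraction; accelerations use central differences,
#' angular velocity comes from the skew part of `Rdot t(R)`, and angular
#' acceleration from differentiating the angular velocity.  Endpoint samples
#' use one-sided differences.
#'
#' @param frames a [build_frames()] result.
#' @param inertia a [segment_inertia()] result.
#' @return list per segment (`arm`, `forearm`, `hand`) with `com`, `v_com`,
#'   `a_com`, `omega`, `alpha` (all `[n, 3]`).
#' @export
derive_motion <- function(frames, inertia) {
  n <- frames$n
  if (n < 5L) stop("need at least 5 samples to differentiate")
  dt <- 1 / frames$rate
  ends <- list(arm = frames$forearm$origin, forearm = frames$hand$origin)
  y_hand <- t(matrix(frames$hand$R[, 2, ], nrow = 3))   # [n, 3] long axis
  ends$hand <- frames$hand$origin - y_hand * inertia$hand$length
  out <- list()
  for (seg in c("arm", "forearm", "hand")) {
    f <- inertia[[seg]]$com_fraction
    com <- frames[[seg]]$origin + f * (ends[[seg]] - frames[[seg]]$origin)
    v <- diff_series(com, dt)
    a <- diff_series(v, dt)
    omega <- matrix(NA_real_, n, 3)
    R <- frames[[seg]]$R
    Rd <- array(NA_real_, c(3, 3, n))
    for (r in 1:3) for (cc in 1:3) {
      e <- matrix(R[r, cc, ], ncol = 1)
      Rd[r, cc, ] <- diff_series(e, dt)
    }
    for (i in seq_len(n)) {
      W <- Rd[, , i] %*% t(R[, , i])
      omega[i, ] <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1],
                      W[2, 1] - W[1, 2]) / 2
    }
    alpha <- diff_series(omega, dt)
    out[[seg]] <- list(com = com, v_com = v, a_com = a,
                       omega = omega, alpha = alpha)
  }
  out
}
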