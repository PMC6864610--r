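# Forward-model simulator of semicircular hand-rim propulsion.
#
# The hand (wrist centre) rides the rim arc during the push, locked to the
# wheel, and returns along a C1 Hermite path dipping below the rim during
# recovery (the semicircular pattern).  Arm posture comes from two-link
# planar inverse kinematics under a fixed shoulder; all 15 model markers are
# placed rigidly on their segments.  Rim kinetics follow a half-sine total
# force split into tangential/radial/axial shares, consistent with the axle
# moment.  Ground truth (segment frames, joint angles, external load, event
# times) is recorded before noise is added.
#
# forward_loads() is an independent Newton-Euler implementation (planar
# closed form, own differentiation) used as the oracle for the pipeline's
# inverse dynamics; it shares no helpers with the analysis modules.

#' Simulation parameters
#'
#' Defaults reproduce the study conditions: treadmill at 0.833 m/s, 600 mm
#' wheel, cadence 1.25 strokes/s, push arc 1 rad centred on top dead centre,
#' peak total rim force 47 N with 75% tangential share, 1 mm marker noise
#' and 0.5 N force noise.
#'
#' @param treadmill_speed m/s.
#' @param wheel_diameter m.
#' @param rim_radius m.
#' @param cadence strokes/s.
#' @param push_arc rad of wheel rotation while gripping, in (0, pi).
#' @param peak_total_force N.
#' @param tangential_share fraction of total force that is tangential (0-1].
#' @param axial_share fraction of total force along the axle.
#' @param anthro an [anthropometry()].
#' @param noise_sd_marker m.
#' @param noise_sd_force N.
#' @param marker_rate,rim_rate Hz.
#' @param wrist_flex_amp_deg amplitude of the wrist flexion oscillation.
#' @param shoulder_offset lab offset of the glenohumeral centre from the
#'   axle, m.
#' @param seed RNG seed for the additive noise.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(treadmill_speed = 0.833, wheel_diameter = 0.600,
                       rim_radius = 0.260, cadence = 1.25, push_arc = 1.0,
                       peak_total_force = 47, tangential_share = 0.75,
                       axial_share = 0.10, anthro = anthropometry(),
                       noise_sd_marker = 0.001, noise_sd_force = 0.5,
                       marker_rate = 50, rim_rate = 240,
                       wrist_flex_amp_deg = 10,
                       shoulder_offset = c(-0.05, 0, 0.65), seed = 1L) {
  if (push_arc <= 0 || push_arc >= pi) stop("push_arc must be in (0, pi)")
  if (tangential_share <= 0 || tangential_share > 1)
    stop("tangential_share must be in (0, 1]")
  if (tangential_share^2 + axial_share^2 > 1)
    stop("tangential_share^2 + axial_share^2 must not exceed 1")
  if (cadence <= 0) stop("cadence must be > 0")
  r_wheel <- wheel_diameter / 2
  Pphase <- push_arc * r_wheel / treadmill_speed
  if (Pphase >= 1 / cadence)
    stop("push phase does not fit in the cycle; reduce push_arc or cadence")
  structure(list(treadmill_speed = treadmill_speed,
                 wheel_diameter = wheel_diameter, rim_radius = rim_radius,
                 cadence = cadence, push_arc = push_arc,
                 peak_total_force = peak_total_force,
                 tangential_share = tangential_share,
                 axial_share = axial_share, anthro = anthro,
                 noise_sd_marker = noise_sd_marker,
                 noise_sd_force = noise_sd_force,
                 marker_rate = marker_rate, rim_rate = rim_rate,
                 wrist_flex_amp_deg = wrist_flex_amp_deg,
                 shoulder_offset = shoulder_offset, seed = seed),
            class = "sim_params")
}

# wrist-centre path in the wheel plane; returns [n, 3] lab positions
sim_wrist_path <- function(t, p, geometry) {
  r_w <- p$wheel_diameter / 2
  r <- p$rim_radius
  ax <- geometry$axle_position
  T <- 1 / p$cadence
  Pp <- p$push_arc * r_w / p$treadmill_speed
  Tr <- T - Pp
  th_HO <- pi / 2 - p$push_arc / 2
  th_HR <- pi / 2 + p$push_arc / 2
  rim_pt <- function(th) cbind(ax[1] - r * cos(th), ax[2], ax[3] + r * sin(th))
  tan_dir <- function(th) cbind(sin(th), 0, cos(th))
  v_hand <- r * p$treadmill_speed / r_w
  tau <- t %% T
  out <- matrix(NA_real_, length(t), 3)
  in_push <- tau < Pp
  th <- th_HO + (p$treadmill_speed / r_w) * tau[in_push]
  out[in_push, ] <- rim_pt(th)
  s <- (tau[!in_push] - Pp) / Tr
  A <- rim_pt(th_HR); B <- rim_pt(th_HO)
  m0 <- v_hand * Tr * tan_dir(th_HR)
  m1 <- v_hand * Tr * tan_dir(th_HO)
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  out[!in_push, ] <- outer(h00, A[1, ]) + outer(h10, m0[1, ]) +
    outer(h01, B[1, ]) + outer(h11, m1[1, ])
  out
}

# planar two-link inverse kinematics with the elbow-back branch;
# returns list of [n, 3]: elbow position plus unit axes of arm and forearm
sim_arm_ik <- function(W, S, L1, L2) {
  d <- sweep(W, 2, S)
  dist <- sqrt(rowSums(d^2))
  if (any(dist > L1 + L2 - 1e-9) || any(dist < abs(L1 - L2) + 1e-9))
    stop("unreachable hand position for given segment lengths")
  A <- acos(pmin(1, pmax(-1, (L1^2 + dist^2 - L2^2) / (2 * L1 * dist))))
  dn <- d / dist
  # rotate the shoulder-hand direction about +y by +A (elbow backward)
  ux <- dn[, 1] * cos(A) + dn[, 3] * sin(A)
  uz <- -dn[, 1] * sin(A) + dn[, 3] * cos(A)
  u <- cbind(ux, 0, uz)
  E <- sweep(L1 * u, 2, S, `+`)
  y_arm <- -u
  y_fore <- (E - W) / L2
  list(E = E, y_arm = y_arm, y_fore = y_fore)
}

planar_frame <- function(y_axis) {
  # frame with z = -y_lab (lateral right), y = given longitudinal axis
  n <- nrow(y_axis)
  R <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) {
    y <- y_axis[i, ] / sqrt(sum(y_axis[i, ]^2))
    z <- c(0, -1, 0)
    x <- c(y[2] * z[3] - y[3] * z[2],
           y[3] * z[1] - y[1] * z[3],
           y[1] * z[2] - y[2] * z[1])
    x <- x / sqrt(sum(x^2))
    R[, , i] <- cbind(x, y, c(x[2] * y[3] - x[3] * y[2],
                              x[3] * y[1] - x[1] * y[3],
                              x[1] * y[2] - x[2] * y[1]))
  }
  R
}

# local Euler decompositions for ground truth (kept separate from the
# analysis module on purpose)
truth_yxy <- function(R)
  c(atan2(R[1, 2], R[3, 2]), acos(max(-1, min(1, R[2, 2]))),
    atan2(R[2, 1], -R[2, 3]))
truth_zxy <- function(R)
  c(atan2(-R[1, 2], R[2, 2]), asin(max(-1, min(1, R[3, 2]))),
    atan2(-R[3, 1], R[3, 3]))

sim_state <- function(t, p, geometry) {
  # full noise-free kinematic state at times t
  S <- geometry$axle_position + p$shoulder_offset
  L1 <- p$anthro$segments$arm$length
  L2 <- p$anthro$segments$forearm$length
  W <- sim_wrist_path(t, p, geometry)
  ik <- sim_arm_ik(W, S, L1, L2)
  T <- 1 / p$cadence
  psi <- p$wrist_flex_amp_deg * pi / 180 * sin(2 * pi * (t %% T) / T)
  # hand longitudinal axis: forearm axis rotated by psi about z = -y_lab
  a <- ik$y_fore[, 1]; c_ <- ik$y_fore[, 3]
  y_hand <- cbind(a * cos(psi) - c_ * sin(psi), 0,
                  a * sin(psi) + c_ * cos(psi))
  list(t = t, S = S, W = W, E = ik$E,
       R_trunk = {
         n <- length(t)
         array(rep(cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)), n),
               c(3, 3, n))
       },
       R_arm = planar_frame(ik$y_arm),
       R_fore = planar_frame(ik$y_fore),
       R_hand = planar_frame(y_hand),
       psi = psi)
}

sim_markers_at <- function(state, p) {
  n <- length(state$t)
  S <- state$S
  labs <- marker_labels()
  pos <- array(NA_real_, c(n, 3, length(labs)),
               dimnames = list(NULL, c("x", "y", "z"), labs))
  put <- function(lab, m) pos[, , lab] <<- m
  rep_row <- function(v) matrix(v, n, 3, byrow = TRUE)
  put("c7", rep_row(S + c(-0.12, 0.25, 0.03)))
  put("acrr", rep_row(S + c(0, -0.05, 0.03)))
  put("acrl", rep_row(S + c(0, 0.55, 0.03)))
  put("hha", rep_row(S + c(0.035, 0, 0)))
  put("hhp", rep_row(S + c(-0.035, 0, 0)))
  # arm cluster and epicondyles, rigid in the arm frame (origin GH = S)
  arm_local <- list(rm1 = c(0.040, -0.12, 0.010),
                    rm2 = c(0.010, -0.16, 0.040),
                    rm3 = c(0.045, -0.20, -0.010))
  for (lab in names(arm_local)) {
    m <- matrix(NA_real_, n, 3)
    for (i in seq_len(n))
      m[i, ] <- S + as.numeric(state$R_arm[, , i] %*% arm_local[[lab]])
    put(lab, m)
  }
  epc <- matrix(NA_real_, n, 3); ipc <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    z_a <- state$R_arm[, 3, i]
    epc[i, ] <- state$E[i, ] + 0.035 * z_a
    ipc[i, ] <- state$E[i, ] - 0.035 * z_a
  }
  put("epc", epc); put("ipc", ipc)
  ulr <- matrix(NA_real_, n, 3); rdl <- matrix(NA_real_, n, 3)
  hand_local <- list("2m" = c(0.012, -0.070, 0.022),
                     "3m" = c(0.000, -0.075, 0.000),
                     "5m" = c(0.008, -0.060, -0.022))
  hl <- lapply(hand_local, function(v) matrix(NA_real_, n, 3))
  for (i in seq_len(n)) {
    z_h <- state$R_hand[, 3, i]
    ulr[i, ] <- state$W[i, ] - 0.025 * z_h
    rdl[i, ] <- state$W[i, ] + 0.025 * z_h
    for (lab in names(hand_local))
      hl[[lab]][i, ] <- state$W[i, ] +
        as.numeric(state$R_hand[, , i] %*% hand_local[[lab]])
  }
  put("ulr", ulr); put("rdl", rdl)
  for (lab in names(hl)) put(lab, hl[[lab]])
  pos
}

sim_rim_kinetics <- function(t, p, geometry) {
  r_w <- p$wheel_diameter / 2
  r <- p$rim_radius
  T <- 1 / p$cadence
  Pp <- p$push_arc * r_w / p$treadmill_speed
  th_HO <- pi / 2 - p$push_arc / 2
  tau <- t %% T
  in_push <- tau < Pp
  ftot <- ifelse(in_push, p$peak_total_force * sin(pi * tau / Pp), 0)
  s_t <- p$tangential_share; s_a <- p$axial_share
  s_r <- sqrt(max(0, 1 - s_t^2 - s_a^2))
  f_tan <- s_t * ftot
  f_rad <- -s_r * ftot      # inward
  f_ax <- s_a * ftot
  theta <- (p$treadmill_speed / r_w) * t
  # sensor storage: formulas at theta recover the physical components
  Fx <- f_rad * cos(theta) - f_tan * sin(theta)
  Fy <- f_rad * sin(theta) + f_tan * cos(theta)
  Fz <- f_ax
  # hand angular position (locked to the wheel during push; recovery: 0 load)
  th_h <- ifelse(in_push, th_HO + (p$treadmill_speed / r_w) * tau, th_HO)
  r_hat <- cbind(-cos(th_h), 0, sin(th_h))
  t_hat <- cbind(sin(th_h), 0, cos(th_h))
  F_lab <- f_rad * r_hat + f_tan * t_hat + cbind(0, f_ax, 0)
  contact <- cbind(geometry$axle_position[1] - r * cos(th_h),
                   geometry$axle_position[2],
                   geometry$axle_position[3] + r * sin(th_h))
  arm_c <- sweep(contact, 2, geometry$axle_position)
  M_lab <- rows_cross(arm_c, F_lab)
  list(F_sensor = cbind(Fx, Fy, Fz),
       M_sensor = cbind(-M_lab[, 1], M_lab[, 3], M_lab[, 2]),
       theta = theta, F_lab = F_lab, M_lab = M_lab, contact = contact,
       f_tan = f_tan, ftot = ftot, hand_angle = th_h)
}

#' Simulate a semicircular propulsion trial
#'
#' @param params a [sim_params()].
#' @param duration trial length, s (must cover at least 2 cycles).
#' @param geometry a [wheelchair_geometry()]; defaults to the parameters'
#'   wheel.
#' @return An object of class `synthetic_trial` with `markers` (at the
#'   marker rate, noisy), `rim` (at the rim rate, noisy), and `truth`
#'   (noise-free ground truth at the rim rate: segment state, joint angles
#'   in degrees, external load on the hand, contact points, event table,
#'   phase durations).
#' @export
simulate_propulsion <- function(params, duration = 8,
                                geometry = wheelchair_geometry(
                                  wheel_diameter = params$wheel_diameter,
                                  rim_radius = params$rim_radius)) {
  p <- params
  T <- 1 / p$cadence
  if (duration < 2 * T) stop("duration must cover at least 2 cycles")
  r_w <- p$wheel_diameter / 2
  Pp <- p$push_arc * r_w / p$treadmill_speed
  t_m <- seq(0, duration, by = 1 / p$marker_rate)
  t_r <- seq(0, duration, by = 1 / p$rim_rate)
  st_m <- sim_state(t_m, p, geometry)
  st_r <- sim_state(t_r, p, geometry)
  kin <- sim_rim_kinetics(t_r, p, geometry)
  # ground-truth joint angles from the analytic frames
  n <- length(t_r)
  ang <- matrix(NA_real_, n, 9)
  colnames(ang) <- c("sh_plane", "sh_elev", "sh_rot",
                     "e_flex", "e_carry", "e_prosup",
                     "wr_flex", "wr_dev", "wr_rot")
  for (i in seq_len(n)) {
    Rt <- st_r$R_trunk[, , i]
    ang[i, 1:3] <- truth_yxy(t(Rt) %*% st_r$R_arm[, , i])
    ang[i, 4:6] <- truth_zxy(t(st_r$R_arm[, , i]) %*% st_r$R_fore[, , i])
    ang[i, 7:9] <- truth_zxy(t(st_r$R_fore[, , i]) %*% st_r$R_hand[, , i])
  }
  ang <- ang * 180 / pi
  # event table from the analytic threshold crossing of the axle moment
  thr <- 1
  amp <- p$rim_radius * p$tangential_share * p$peak_total_force
  tau_on <- Pp / pi * asin(min(1, thr / amp))
  k_max <- floor(duration / T) - 1L
  ks <- 0:k_max
  events <- cbind(
    i_on = floor((ks * T + tau_on) * p$rim_rate) + 2L,
    i_off = floor((ks * T + Pp - tau_on) * p$rim_rate) + 2L,
    i_HO_nominal = round(ks * T * p$rim_rate) + 1L)
  events <- events[events[, "i_off"] <= n, , drop = FALSE]
  # additive noise, seeded; ground truth recorded before this point
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(p$seed)
  pos <- sim_markers_at(st_m, p)
  pos_noisy <- pos + array(stats::rnorm(length(pos), 0, p$noise_sd_marker),
                           dim(pos))
  F_noisy <- kin$F_sensor +
    matrix(stats::rnorm(3 * n, 0, p$noise_sd_force), n, 3)
  M_noisy <- kin$M_sensor +
    matrix(stats::rnorm(3 * n, 0, p$noise_sd_force * p$rim_radius), n, 3)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  markers <- marker_series(pos_noisy, marker_labels(), p$marker_rate)
  rim <- handrim_series(F_noisy, M_noisy, kin$theta, p$rim_rate, "right")
  truth <- list(t = t_r, state = st_r, angles = ang,
                F_on_hand = -kin$F_lab, contact = kin$contact,
                hand_angle = kin$hand_angle,
                f_tan = kin$f_tan, ftot = kin$ftot,
                events = events, Pphase = Pp, Rphase = T - Pp,
                cadence = p$cadence,
                markers_clean = pos, rim_clean = kin)
  structure(list(markers = markers, rim = rim, truth = truth,
                 params = p, geometry = geometry),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_trial: %.1f s, cadence %.2f st/s, speed %.3f m/s\n",
    "  %d complete pushes; peak force %.1f N (tangential share %.2f)\n"),
    length(x$truth$t) / x$params$rim_rate, x$params$cadence,
    x$params$treadmill_speed, nrow(x$truth$events),
    x$params$peak_total_force, x$params$tangential_share))
  invisible(x)
}

#' Ground-truth joint loads by forward Newton-Euler
#'
#' Independent oracle for the inverse-dynamics pipeline: works from the
#' simulator's analytic segment state, uses the planar closed form for the
#' angular terms, and its own finite differences.  Valid only for the
#' planar trials this simulator produces.
#'
#' @param trial a [simulate_propulsion()] result (noise-free truth is used).
#' @param inertia a [segment_inertia()] result.
#' @return list per joint (`wrist`, `elbow`, `shoulder`) with `F`, `M`
#'   (`[n, 3]`, lab axes), on the rim timebase.
#' @export
forward_loads <- function(trial, inertia) {
  st <- trial$truth$state
  n <- length(st$t)
  dt <- 1 / trial$params$rim_rate
  g <- c(0, 0, -9.81)
  # planarity check: lateral axes must stay along -y_lab
  if (max(abs(st$R_arm[2, 3, ] + 1)) > 1e-9)
    stop("forward_loads requires a planar trial")
  d1 <- function(x) {
    n <- nrow(x); d <- x * 0
    if (n >= 3) d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] -
                                   x[1:(n - 2), , drop = FALSE]) / (2 * dt)
    d[1, ] <- (x[2, ] - x[1, ]) / dt
    d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
    d
  }
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  L_h <- inertia$hand$length
  y_h <- t(matrix(st$R_hand[, 2, ], nrow = 3))
  origins <- list(hand = st$W, forearm = st$E,
                  arm = matrix(st$S, n, 3, byrow = TRUE))
  ends <- list(hand = st$W - L_h * y_h, forearm = st$W, arm = st$E)
  Rs <- list(hand = st$R_hand, forearm = st$R_fore, arm = st$R_arm)
  F_dist <- trial$truth$F_on_hand
  M_dist <- matrix(0, n, 3)
  p_dist <- trial$truth$contact
  out <- list()
  jn <- c(hand = "wrist", forearm = "elbow", arm = "shoulder")
  for (seg in c("hand", "forearm", "arm")) {
    m <- inertia[[seg]]$mass
    f <- inertia[[seg]]$com_fraction
    com <- origins[[seg]] + f * (ends[[seg]] - origins[[seg]])
    acc <- d1(d1(com))
    # planar angular terms: rotation about lab y, transverse inertia
    yax <- t(matrix(Rs[[seg]][, 2, ], nrow = 3))
    chi <- unwrap_angle(atan2(yax[, 1], yax[, 3]))
    chidd <- d1(d1(matrix(chi, ncol = 1)))
    It <- inertia[[seg]]$I_local[1, 1]
    M_inert <- cbind(0, It * chidd[, 1], 0)
    Fj <- m * acc - matrix(m * g, n, 3, byrow = TRUE) - F_dist
    Mj <- M_inert - M_dist - cr(p_dist - com, F_dist) -
      cr(origins[[seg]] - com, Fj)
    out[[jn[[seg]]]] <- list(F = Fj, M = Mj)
    F_dist <- -Fj; M_dist <- -Mj; p_dist <- origins[[seg]]
  }
  out
}

#' Simulate a two-group cohort of hand-rim summaries
#'
#' Fixture kit for the group-comparison stage: one lower-force group
#' ("P", peak total force around 47 N, high tangential share) and one
#' higher-force group ("T", around 93 N, lower share), each subject a short
#' simulated trial run through event detection and the hand-rim summaries.
#'
#' @param n_per_group subjects per group.
#' @param seed base RNG seed.
#' @param duration per-subject trial length, s.
#' @return data.frame with `subject`, `group` and hand-rim kinetic columns.
#' @export
simulate_two_groups <- function(n_per_group = 5, seed = 1L, duration = 4) {
  rows <- list()
  specs <- list(P = list(peak = 47, share = 0.76, sd_peak = 6),
                T = list(peak = 93, share = 0.49, sd_peak = 12))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  subject_seeds <- sample.int(2^30, 2 * n_per_group)
  draws <- list(peak = stats::rnorm(2 * n_per_group),
                cad = stats::runif(2 * n_per_group, 1.0, 1.3))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  k <- 0
  for (grp in names(specs)) {
    sp <- specs[[grp]]
    for (i in seq_len(n_per_group)) {
      k <- k + 1
      peak <- max(20, sp$peak + sp$sd_peak * draws$peak[k])
      p <- sim_params(peak_total_force = peak, tangential_share = sp$share,
                      cadence = draws$cad[k], seed = subject_seeds[k])
      tr <- simulate_propulsion(p, duration = duration)
      mz <- lowpass_zero_phase(tr$rim$M[, 3], tr$rim$rate, 20, 4)
      pushes <- detect_pushes(mz, 1, tr$rim$rate)
      cyc <- segment_cycles(pushes, tr$rim$rate)
      if (!length(cyc)) next
      hs <- summarize_handrim_cycles(tr$rim, cyc)
      rows[[k]] <- data.frame(subject = sprintf("%s%02d", grp, i),
                              group = grp,
                              Ftot_max = hs$Ftot_max,
                              Ftang_max = hs$Ftang_max,
                              Feff = hs$Feff, ERF = hs$ERF,
                              Mtot_max = hs$Mtot_max, ERM = hs$ERM,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
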