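# random constant-pose fixture shared by the dynamics and acceptance tests

static_pose_case <- function(inertia, F_ext = c(0, 0, 0), at_top = FALSE) {
  # random constant pose; returns frames, rim series and oracle loads
  S <- c(stats::rnorm(1, 0, 0.1), -0.25, stats::rnorm(1, 1.0, 0.05))
  R_arm <- random_rotation(); R_fore <- random_rotation()
  R_hand <- random_rotation()
  E <- S + R_arm[, 2] * -inertia$arm$length
  W <- E + R_fore[, 2] * -inertia$forearm$length
  geo <- wheelchair_geometry()
  if (at_top) {
    # place the wrist exactly above the axle so the contact angle is pi/2
    W <- geo$axle_position + c(0, 0, geo$rim_radius)
    E <- W + c(0.1, 0, 0.25)
    S <- E + c(-0.05, 0, 0.28)
    R_arm <- diag(3); R_fore <- diag(3); R_hand <- diag(3)
  }
  n <- 9
  frames <- static_frames(
    list(trunk = diag(3), arm = R_arm, forearm = R_fore, hand = R_hand),
    list(trunk = S + c(0, 0.25, 0.03), arm = S, forearm = E, hand = W),
    n = n)
  hand_end <- W - R_hand[, 2] * inertia$hand$length
  coms <- list(
    hand = W + inertia$hand$com_fraction * (hand_end - W),
    forearm = E + inertia$forearm$com_fraction * (W - E),
    arm = S + inertia$arm$com_fraction * (E - S))
  # rim stream producing the requested lab-frame hand load:
  # wrist above the axle -> radial direction is +z, theta = 0 stored
  f_rad <- if (at_top) -F_ext[3] else 0
  rim <- handrim_series(matrix(rep(c(f_rad, 0, 0), each = n), n, 3),
                        matrix(0, n, 3), rep(0, n), 240, "right")
  masses <- list(hand = inertia$hand$mass, forearm = inertia$forearm$mass,
                 arm = inertia$arm$mass)
  contact <- geo$axle_position + c(0, 0, geo$rim_radius)
  oracle <- oracle_static_loads(coms, list(W, E, S), masses,
                                F_ext = F_ext, p_ext = contact)
  list(frames = frames, rim = rim, geo = geo, oracle = oracle)
}
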