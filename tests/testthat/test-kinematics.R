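test_that("cluster calibration and reconstruction recover rigid motion", {
  # synthetic cluster: well-spread reference triangle plus two dependents
  ref_local <- rbind(c(0, 0, 0), c(0.12, 0, 0), c(0.04, 0.10, 0.02))
  dep_local <- rbind(c(0.05, 0.03, -0.08), c(-0.02, 0.06, 0.05))
  place <- function(R, t) list(
    ref = sweep(ref_local %*% t(R), 2, t, `+`),
    dep = sweep(dep_local %*% t(R), 2, t, `+`))
  mk_series <- function(frames) {
    n <- length(frames)
    pos <- array(NA_real_, c(n, 3, 5),
                 dimnames = list(NULL, NULL,
                                 c("rm1", "rm2", "rm3", "epc", "ipc")))
    for (i in seq_len(n)) {
      pos[i, , 1:3] <- t(frames[[i]]$ref)
      pos[i, , 4:5] <- t(frames[[i]]$dep)
    }
    marker_series(pos, c("rm1", "rm2", "rm3", "epc", "ipc"), 50)
  }
  cl <- list(arm = list(reference = c("rm1", "rm2", "rm3"),
                        dependent = c("epc", "ipc")))
  # translation invariance of the template
  st1 <- mk_series(list(place(diag(3), c(0, 0, 0))))
  st2 <- mk_series(list(place(diag(3), c(1, 0, 0))))
  t1 <- calibrate_cluster(st1, cl)$arm
  t2 <- calibrate_cluster(st2, cl)$arm
  expect_equal(t1$dep_local, t2$dep_local, tolerance = 1e-12)
  # identity reconstruction
  rec <- reconstruct_markers(calibrate_cluster(st1, cl), st1)
  expect_equal(rec$positions[1, , "epc"], st1$positions[1, , "epc"],
               tolerance = 1e-12, ignore_attr = TRUE)
  # exact 90-degree rotation about z
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  dyn <- mk_series(list(place(Rz90, c(0.3, 0.1, 0))))
  rec90 <- reconstruct_markers(calibrate_cluster(st1, cl), dyn)
  expect_equal(rec90$positions[1, , "epc"], dyn$positions[1, , "epc"],
               tolerance = 1e-9, ignore_attr = TRUE)
  # random rigid placements reapply exactly
  set.seed(3)
  for (k in 1:10) {
    R <- random_rotation(); tt <- stats::rnorm(3)
    dynk <- mk_series(list(place(R, tt)))
    reck <- reconstruct_markers(calibrate_cluster(st1, cl), dynk)
    expect_lt(max(abs(reck$positions[1, , 4:5] - dynk$positions[1, , 4:5])),
              1e-9)
  }
  # collinear reference markers are rejected
  bad_local <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0))
  badf <- st1
  badf$positions[1, , 1:3] <- t(bad_local)
  bad <- marker_series(badf$positions, badf$labels, 50)
  expect_error(calibrate_cluster(bad, cl), "collinear")
})

test_that("reconstruction under 1 mm marker noise stays below 2 mm RMS", {
  ref_local <- rbind(c(0, 0, 0), c(0.12, 0, 0), c(0.04, 0.10, 0.02))
  dep_local <- rbind(c(0.05, 0.03, -0.08), c(-0.02, 0.06, 0.05))
  labs <- c("rm1", "rm2", "rm3", "epc", "ipc")
  n <- 1000
  set.seed(21)
  pos <- array(NA_real_, c(n, 3, 5), dimnames = list(NULL, NULL, labs))
  truth <- array(NA_real_, c(n, 3, 2))
  for (i in seq_len(n)) {
    R <- random_rotation(); tt <- stats::rnorm(3, 0, 0.5)
    ref <- sweep(ref_local %*% t(R), 2, tt, `+`)
    dep <- sweep(dep_local %*% t(R), 2, tt, `+`)
    pos[i, , 1:3] <- t(ref + matrix(stats::rnorm(9, 0, 0.001), 3, 3))
    pos[i, , 4:5] <- NA  # dependents unobserved
    truth[i, , ] <- t(dep)
  }
  pos[, , 4:5] <- 0  # placeholder; reconstruction overwrites
  dyn <- marker_series(pos, labs, 50)
  # calibrate from a noise-free static frame
  st <- array(NA_real_, c(1, 3, 5), dimnames = list(NULL, NULL, labs))
  st[1, , 1:3] <- t(ref_local); st[1, , 4:5] <- t(dep_local)
  tpl <- calibrate_cluster(marker_series(st, labs, 50),
                           list(arm = list(reference = labs[1:3],
                                           dependent = labs[4:5])))
  rec <- reconstruct_markers(tpl, dyn)
  err <- rec$positions[, , 4:5] - truth
  expect_lt(sqrt(mean(err^2)), 0.002)
})

test_that("Euler compose/decompose round trips and constructed rotations", {
  # elbow flexed 90 degrees about the flexion axis
  expect_equal(euler_zxy_angles(euler_zxy(pi / 2, 0, 0)),
               c(pi / 2, 0, 0), tolerance = 1e-12)
  expect_equal(euler_yxy_angles(diag(3)), c(0, 0, 0))
  set.seed(5)
  for (k in 1:500) {
    a <- c(stats::runif(1, -pi + 0.01, pi - 0.01),
           stats::runif(1, 0.05, pi - 0.05),
           stats::runif(1, -pi + 0.01, pi - 0.01))
    expect_equal(euler_yxy_angles(euler_yxy(a[1], a[2], a[3])), a,
                 tolerance = 1e-9)
    b <- c(stats::runif(1, -pi + 0.01, pi - 0.01),
           stats::runif(1, -pi / 2 + 0.05, pi / 2 - 0.05),
           stats::runif(1, -pi + 0.01, pi - 0.01))
    expect_equal(euler_zxy_angles(euler_zxy(b[1], b[2], b[3])), b,
                 tolerance = 1e-9)
  }
})

test_that("segment frames: orthonormality, anatomical identity, equivariance", {
  mk <- anatomical_markers()
  fr <- build_frames(mk)
  # anatomical pose: trunk and arm frames coincide (identity relative rotation)
  expect_equal(t(fr$trunk$R[, , 1]) %*% fr$arm$R[, , 1], diag(3),
               tolerance = 1e-9)
  expect_equal(t(fr$arm$R[, , 1]) %*% fr$forearm$R[, , 1], diag(3),
               tolerance = 1e-9)
  tr <- clean_trial_240()
  frt <- build_frames(tr$markers)
  for (i in seq(1, frt$n, by = 97))
    for (seg in c("trunk", "arm", "forearm", "hand")) {
      R <- frt[[seg]]$R[, , i]
      expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
      expect_equal(det(R), 1, tolerance = 1e-9)
    }
  # whole-lab rotation left-multiplies every frame, angles unchanged
  set.seed(9)
  Q <- random_rotation()
  mkr <- mk
  for (lab in mk$labels)
    mkr$positions[, , lab] <- mk$positions[, , lab] %*% t(Q)
  mkr <- marker_series(mkr$positions, mk$labels, mk$rate)
  frr <- build_frames(mkr)
  for (seg in c("trunk", "arm", "forearm", "hand"))
    expect_equal(frr[[seg]]$R[, , 1], Q %*% fr[[seg]]$R[, , 1],
                 tolerance = 1e-9)
  # elbow/wrist angles unchanged (shoulder sits at its sequence singularity
  # in this pose, where the decomposition branch is not unique)
  expect_equal(joint_angles(frr)$angles[, 4:9], joint_angles(fr)$angles[, 4:9],
               tolerance = 1e-6)
})

test_that("pipeline joint angles match simulator ground truth", {
  tr <- clean_trial_240()
  ja <- joint_angles(build_frames(tr$markers))
  expect_lt(max(abs(ja$angles - tr$truth$angles)), 1e-6)
})

test_that("motion derivatives: circular motion and constant spin", {
  rate <- 240
  n <- 480
  t <- (seq_len(n) - 1) / rate
  omega <- 4; r <- 0.3
  circ <- cbind(r * cos(omega * t), r * sin(omega * t), 0)
  mk_fr <- function(origin_list, R_fun = function(i) diag(3)) {
    f <- list()
    for (seg in c("trunk", "arm", "forearm", "hand")) {
      R <- array(NA_real_, c(3, 3, n))
      for (i in seq_len(n)) R[, , i] <- R_fun(i)
      f[[seg]] <- list(R = R, origin = origin_list[[seg]])
    }
    structure(c(f, list(rate = rate, n = n)), class = "segment_frames")
  }
  still <- matrix(0, n, 3)
  inertia <- segment_inertia(anthropometry())
  # hand origin and distal end co-move on the circle -> COM on the circle
  fr <- mk_fr(list(trunk = still, arm = still, forearm = still,
                   hand = circ))
  mo <- derive_motion(fr, inertia)
  # interior samples: |a| = omega^2 * r_com, r_com scaled by com offset
  a_mag <- sqrt(rowSums(mo$hand$a_com[10:(n - 10), ]^2))
  # COM lies between origin (circle) and distal end (shifted circle):
  # with identity rotation the distal offset is constant, so a = -w^2 p
  expect_equal(mean(a_mag), omega^2 * r, tolerance = 0.01 * omega^2 * r)
  # stationary segment: all derivatives zero
  mo0 <- derive_motion(mk_fr(list(trunk = still, arm = still,
                                  forearm = still, hand = still)), inertia)
  expect_lt(max(abs(mo0$arm$a_com)), 1e-9)
  expect_lt(max(abs(mo0$arm$omega)), 1e-9)
  # constant spin about z
  spin <- mk_fr(list(trunk = still, arm = still, forearm = still,
                     hand = still),
                R_fun = function(i) {
                  a <- omega * (i - 1) / rate
                  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                         3, 3)
                })
  mos <- derive_motion(spin, inertia)
  expect_equal(mos$hand$omega[n %/% 2, ], c(0, 0, omega), tolerance = 1e-3)
})
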