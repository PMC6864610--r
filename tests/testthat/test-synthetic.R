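test_that("same seed gives bit-identical trials", {
  p <- sim_params(seed = 99L)
  t1 <- simulate_propulsion(p, duration = 3)
  t2 <- simulate_propulsion(p, duration = 3)
  expect_identical(t1$markers$positions, t2$markers$positions)
  expect_identical(t1$rim$F, t2$rim$F)
  expect_identical(t1$rim$M, t2$rim$M)
  t3 <- simulate_propulsion(sim_params(seed = 100L), duration = 3)
  expect_false(identical(t1$markers$positions, t3$markers$positions))
})

test_that("cadence 1.25 over 4 s yields exactly 5 cycles downstream", {
  p <- sim_params(noise_sd_marker = 0, noise_sd_force = 0, cadence = 1.25)
  tr <- simulate_propulsion(p, duration = 4.2)
  mz <- lowpass_zero_phase(tr$rim$M[, 3], 240, 20, 4)
  cyc <- segment_cycles(detect_pushes(mz, 1, 240), 240)
  expect_length(cyc, 4)   # 5 complete pushes -> 4 HO-to-HO cycles
  tr8 <- clean_trial()
  mz8 <- lowpass_zero_phase(tr8$rim$M[, 3], 240, 20, 4)
  cyc8 <- segment_cycles(detect_pushes(mz8, 1, 240), 240)
  expect_gte(length(cyc8), 5)
})

test_that("event detection reproduces generator event indices within 1 sample", {
  tr <- clean_trial()
  pushes <- detect_pushes(tr$rim$M[, 3], 1, 240)
  ev <- tr$truth$events
  k <- min(nrow(pushes), nrow(ev))
  expect_lte(max(abs(pushes[1:k, "i_on"] - ev[1:k, "i_on"])), 1)
  expect_lte(max(abs(pushes[1:k, "i_off"] - ev[1:k, "i_off"])), 1)
})

test_that("marker rigidity: intra-segment distances constant before noise", {
  tr <- clean_trial()
  pos <- tr$truth$markers_clean
  dists <- function(a, b) sqrt(rowSums((pos[, , a] - pos[, , b])^2))
  for (pair in list(c("rm1", "rm2"), c("rm2", "rm3"), c("rm1", "epc"),
                    c("epc", "ipc"), c("ulr", "rdl"), c("3m", "ulr"),
                    c("2m", "5m"), c("c7", "acrr"), c("hha", "hhp"))) {
    d <- dists(pair[1], pair[2])
    expect_lt(max(d) - min(d), 1e-12)
  }
})

test_that("rim moment equals tangential force times rim radius during push", {
  tr <- clean_trial()
  ftan <- tangential_force(tr$rim$F, tr$rim$theta)
  push <- which(tr$truth$ftot > 1)
  expect_equal(tr$rim$M[push, 3], tr$geometry$rim_radius * ftan[push],
               tolerance = 1e-9, ignore_attr = TRUE)
  # generated tangential profile matches the recorded truth
  expect_equal(ftan, tr$truth$f_tan, tolerance = 1e-9)
})

test_that("per-cycle rim work matches the half-sine closed form", {
  tr <- clean_trial()
  p <- tr$params
  T <- 1 / p$cadence
  i0 <- round(2 * T * 240) + 1; i1 <- round(3 * T * 240) + 1
  # work = integral of Mz dtheta over one cycle
  mz <- tr$rim$M[, 3]
  W_meas <- sum((mz[i0:(i1 - 1)] + mz[(i0 + 1):i1]) / 2 *
                diff(tr$rim$theta[i0:i1]))
  A_tan <- p$tangential_share * p$peak_total_force
  W_true <- 2 * A_tan * tr$truth$Pphase / pi * p$rim_radius *
    (p$treadmill_speed / (p$wheel_diameter / 2))
  expect_equal(W_meas, W_true, tolerance = 0.05 * W_true)
})

test_that("forward loads: statics limit and mass linearity", {
  # zero-speed-like check via a trial with tiny forces: gravity dominates
  p <- sim_params(noise_sd_marker = 0, noise_sd_force = 0,
                  peak_total_force = 1e-9)
  tr <- simulate_propulsion(p, duration = 2)
  inertia <- segment_inertia(p$anthro)
  fl <- forward_loads(tr, inertia)
  masses <- c(inertia$hand$mass, inertia$forearm$mass, inertia$arm$mass)
  # average vertical joint force over the trial ~ supported weight
  int <- 50:(length(tr$truth$t) - 50)
  expect_equal(mean(fl$wrist$F[int, 3]), masses[1] * 9.81,
               tolerance = 0.05 * masses[1] * 9.81)
  expect_equal(mean(fl$shoulder$F[int, 3]), sum(masses) * 9.81,
               tolerance = 0.05 * sum(masses) * 9.81)
  # doubling all masses doubles gravitational joint forces in the mean
  a2 <- p$anthro
  for (s in names(a2$segments)) a2$segments[[s]]$mass <-
      2 * a2$segments[[s]]$mass
  fl2 <- forward_loads(tr, segment_inertia(a2))
  expect_equal(mean(fl2$shoulder$F[int, 3]),
               2 * mean(fl$shoulder$F[int, 3]), tolerance = 1e-6)
})

test_that("shoulder force shows a single in-push peak per cycle", {
  tr <- clean_trial()
  inertia <- segment_inertia(tr$params$anthro)
  fl <- forward_loads(tr, inertia)
  fmag <- sqrt(rowSums(fl$shoulder$F^2))
  ev <- tr$truth$events
  T <- 1 / tr$params$cadence
  for (k in 2:4) {
    cyc_idx <- ev[k, "i_HO_nominal"]:(ev[k + 1, "i_HO_nominal"] - 1)
    i_pk <- cyc_idx[which.max(fmag[cyc_idx])]
    expect_true(i_pk >= ev[k, "i_on"] - 5 && i_pk <= ev[k, "i_off"] + 5)
  }
})

test_that("two-group fixture kit separates hand-rim force scales", {
  kit <- simulate_two_groups(n_per_group = 3, seed = 2L, duration = 3)
  expect_equal(nrow(kit), 6)
  expect_true(all(c("Ftot_max", "Feff") %in% names(kit)))
  expect_gt(mean(kit$Ftot_max[kit$group == "T"]),
            mean(kit$Ftot_max[kit$group == "P"]))
  expect_gt(mean(kit$Feff[kit$group == "P"]),
            mean(kit$Feff[kit$group == "T"]))
  # deterministic in the seed
  kit2 <- simulate_two_groups(n_per_group = 3, seed = 2L, duration = 3)
  expect_identical(kit, kit2)
})

test_that("simulator rejects impossible configurations", {
  expect_error(sim_params(push_arc = 4), "push_arc")
  expect_error(sim_params(tangential_share = 0), "tangential_share")
  expect_error(sim_params(cadence = 3), "push phase")
  expect_error(simulate_propulsion(sim_params(), duration = 1), "2 cycles")
  # unreachable geometry: shoulder too far from the rim
  p <- sim_params(shoulder_offset = c(-0.4, 0, 1.2))
  expect_error(simulate_propulsion(p, duration = 2), "unreachable")
})
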