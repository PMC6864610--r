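test_that("push detection matches a per-sample threshold scan", {
  rate <- 240
  # square wave 0 <-> 5 Nm, 1 s period
  m <- rep(c(rep(0, 120), rep(5, 120)), 4)
  got <- detect_pushes(m, 1, rate)
  expect_equal(got, oracle_push_scan(m, 1, rate, 0.1))
  expect_equal(nrow(got), 3)      # last push has a falling edge; first is at 121
  # all below threshold
  expect_equal(nrow(detect_pushes(rep(0.5, 500), 1, rate)), 0)
  # ramp ending above threshold: incomplete push discarded
  expect_equal(nrow(detect_pushes(seq(0, 5, length.out = 300), 1, rate)), 0)
  # property: 100 random smooth signals
  set.seed(7)
  for (k in 1:100) {
    m <- as.numeric(stats::filter(stats::rnorm(400, 0.8, 1.5),
                                  rep(0.2, 5), sides = 2))
    m[is.na(m)] <- 0
    expect_identical(detect_pushes(m, 1, rate, min_push_s = 0),
                     oracle_push_scan(m, 1, rate, 0))
  }
})

test_that("debounce drops sub-minimum pushes", {
  rate <- 240
  m <- rep(0, 500)
  m[100:110] <- 5        # 11 samples ~ 0.046 s: dropped at 0.1 s minimum
  m[200:240] <- 5        # 41 samples ~ 0.17 s: kept
  got <- detect_pushes(m, 1, rate, min_push_s = 0.1)
  expect_equal(nrow(got), 1)
  expect_equal(unname(got[1, "i_on"]), 200L)
})

test_that("cycle segmentation arithmetic and phase partition", {
  pushes <- cbind(i_on = c(1L, 241L), i_off = c(101L, 341L))
  cyc <- segment_cycles(pushes, 240)
  expect_length(cyc, 1)
  expect_equal(cyc[[1]]$Pphase, 100 / 240)
  expect_equal(cyc[[1]]$Rphase, 140 / 240)
  expect_equal(cyc[[1]]$Pphase + cyc[[1]]$Rphase,
               (cyc[[1]]$i_end - cyc[[1]]$i_HO) / 240)
  expect_length(segment_cycles(pushes[1, , drop = FALSE], 240), 0)
  # six pushes -> five cycles, each partitioning its duration
  tr <- clean_trial()
  mz <- lowpass_zero_phase(tr$rim$M[, 3], 240, 20, 4)
  cyc <- segment_cycles(detect_pushes(mz, 1, 240), 240)
  expect_gte(length(cyc), 5)
  for (cy in cyc)
    expect_equal(cy$Pphase + cy$Rphase, (cy$i_end - cy$i_HO) / 240,
                 tolerance = 1e-12)
})

test_that("cycle selection respects the analysis window", {
  mk_cycle <- function(t0, rate = 240) {
    i0 <- as.integer(t0 * rate) + 1L
    structure(list(i_HO = i0, i_HR = i0 + 80L, i_end = i0 + 192L,
                   Pphase = 80 / rate, Rphase = 112 / rate, rate = rate),
              class = "propulsion_cycle")
  }
  cycles <- lapply(seq(0, by = 0.8, length.out = 8), mk_cycle)
  expect_identical(select_cycles(cycles, c(0, Inf), 5), cycles[1:5])
  expect_error(select_cycles(cycles[1:3], c(0, Inf), 5), "found 3")
  # window starting after the second cycle picks cycles 3..7
  sel <- select_cycles(cycles, c(1.6, Inf), 5)
  expect_identical(sel, cycles[3:7])
})

test_that("propulsion instants: top centre, follow-through, arm preparation", {
  tr <- clean_trial_240()
  geo <- tr$geometry
  mz <- tr$rim$M[, 3]
  cyc <- segment_cycles(detect_pushes(mz, 1, 240), 240)
  wc <- (marker_xyz(tr$markers, "ulr") + marker_xyz(tr$markers, "rdl")) / 2
  m3 <- marker_xyz(tr$markers, "3m")
  cy <- locate_instants(cyc[[2]], m3, geo, contact_xyz = wc)
  # generator apex: mid-push of the nominal cycle
  k <- 2
  T <- 1 / tr$params$cadence
  i_tc_true <- round((( k - 1) * T + tr$truth$Pphase / 2) * 240) + 1
  expect_lte(abs(cy$i_TC - i_tc_true), 1)
  expect_true(cy$i_FT >= cy$i_HO && cy$i_FT <= cy$i_end)
  # FT anterior of AR by construction of the semicircular path
  expect_gt(m3[cy$i_FT, 1], m3[cy$i_AR, 1])
  # constant hand position: earliest-index tie-break
  const <- matrix(0.3, 600, 3)
  cy0 <- structure(list(i_HO = 10L, i_HR = 100L, i_end = 200L,
                        Pphase = 90 / 240, Rphase = 100 / 240, rate = 240),
                   class = "propulsion_cycle")
  cyc0 <- locate_instants(cy0, const, geo)
  expect_equal(cyc0$i_FT, 10L)
  expect_equal(cyc0$i_AR, 10L)
  # strictly increasing x: FT last, AR first
  inc <- cbind(seq(0, 1, length.out = 600), 0, 0.5)
  cyi <- locate_instants(cy0, inc, geo)
  expect_equal(cyi$i_FT, 200L)
  expect_equal(cyi$i_AR, 10L)
})

test_that("cycle normalization is linear interpolation with exact endpoints", {
  cy <- structure(list(i_HO = 11L, i_HR = 61L, i_end = 131L,
                       Pphase = 50 / 240, Rphase = 70 / 240, rate = 240),
                  class = "propulsion_cycle")
  x <- rep(2.5, 200)
  expect_equal(normalize_cycle(x, cy, 101), rep(2.5, 101))
  ramp <- seq(0, 199) / 120
  tr <- normalize_cycle(ramp, cy, 101)
  expect_equal(tr, seq(ramp[11], ramp[131], length.out = 101),
               tolerance = 1e-12)
  sine <- sin(seq(0, 6, length.out = 200))
  got <- normalize_cycle(sine, cy, 101)
  stations <- seq(11, 131, length.out = 101)
  brute <- vapply(stations, function(s) {
    i <- floor(s); w <- s - i
    if (w == 0) sine[i] else (1 - w) * sine[i] + w * sine[i + 1]
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_identical(c(got[1], got[101]), c(sine[11], sine[131]))
  expect_error(normalize_cycle(sine, cy, 1), "n_points")
})

test_that("temporal-spatial variables", {
  # 5 cycles spanning exactly 4 s -> PF 1.25; symmetric phases -> ratio 1
  rate <- 240
  mk_cycle <- function(i0) structure(
    list(i_HO = i0, i_HR = i0 + 96L, i_end = i0 + 192L,
         Pphase = 0.4, Rphase = 0.4, rate = rate),
    class = "propulsion_cycle")
  cycles <- lapply(as.integer(seq(1, by = 192, length.out = 5)), mk_cycle)
  n <- 1200
  theta <- seq(0, by = 2.4 / 192, length.out = n)   # 2.4 rad per cycle
  rim <- handrim_series(matrix(0, n, 3), matrix(0, n, 3), theta, rate,
                        "right")
  geo <- wheelchair_geometry(wheel_diameter = 0.600)
  ts <- temporal_spatial(cycles, rim, geo)
  expect_equal(ts$PF, 5 / 4)
  expect_equal(ts$ratio, 1.0)
  expect_equal(ts$Dist, 0.3 * 2.4, tolerance = 1e-9)   # 0.72 m
  expect_error(temporal_spatial(list(), rim, geo), "empty")
})
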