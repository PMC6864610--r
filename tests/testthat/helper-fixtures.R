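# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache))
    assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

clean_trial <- function() cached("clean_trial", {
  simulate_propulsion(sim_params(noise_sd_marker = 0, noise_sd_force = 0),
                      duration = 8)
})

clean_trial_240 <- function() cached("clean_trial_240", {
  simulate_propulsion(sim_params(noise_sd_marker = 0, noise_sd_force = 0,
                                 marker_rate = 240), duration = 6)
})

clean_analysis <- function() cached("clean_analysis", {
  tr <- clean_trial()
  suppressWarnings(analyze_trial(tr$markers, tr$rim, study_config(),
                                 tr$params$anthro, tr$geometry))
})

# constant-pose frames object (n samples) from explicit segment rotations
# and joint centres; hand distal length from inertia is used by the caller
static_frames <- function(R_list, origins, n = 9, rate = 240) {
  f <- list()
  for (seg in c("trunk", "arm", "forearm", "hand")) {
    R <- array(rep(R_list[[seg]], n), c(3, 3, n))
    o <- matrix(origins[[seg]], n, 3, byrow = TRUE)
    f[[seg]] <- list(R = R, origin = o)
  }
  structure(c(f, list(rate = rate, n = n)), class = "segment_frames")
}

zero_rim <- function(n, rate = 240)
  handrim_series(matrix(0, n, 3), matrix(0, n, 3), rep(0, n), rate, "right")

# marker series where every marker sits on its nominal anatomical-pose
# position (arm hanging, lab-aligned segment axes)
anatomical_markers <- function(n = 5, rate = 50) {
  S <- c(0, -0.25, 1.0)
  E <- S + c(0, 0, -0.30)
  W <- E + c(0, 0, -0.28)
  pos <- array(NA_real_, c(n, 3, 15),
               dimnames = list(NULL, c("x", "y", "z"), marker_labels()))
  put <- function(lab, v) for (i in 1:n) pos[i, , lab] <<- v
  put("c7", S + c(-0.12, 0.25, 0.03))
  put("acrr", S + c(0, -0.05, 0.03)); put("acrl", S + c(0, 0.55, 0.03))
  put("hha", S + c(0.035, 0, 0)); put("hhp", S + c(-0.035, 0, 0))
  put("rm1", S + c(0.04, -0.03, -0.12)); put("rm2", S + c(0.01, 0.02, -0.16))
  put("rm3", S + c(0.05, -0.01, -0.20))
  put("epc", E + c(0, -0.035, 0)); put("ipc", E + c(0, 0.035, 0))
  put("ulr", W + c(0, 0.025, 0)); put("rdl", W + c(0, -0.025, 0))
  put("2m", W + c(0.012, -0.022, -0.070))
  put("3m", W + c(0, 0, -0.075))
  put("5m", W + c(0.008, 0.022, -0.060))
  marker_series(pos, marker_labels(), rate)
}
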