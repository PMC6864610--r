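# End-to-end propulsion analysis and JSON reporting.

#' Analyze one propulsion trial
#'
#' Full pipeline: gap filling, zero-phase low-pass filtering of the kinetic
#' streams (and, at a lower cutoff, of the marker trajectories before
#' differentiation), synchronization onto the kinetic timebase, push
#' detection on the axle moment, cycle selection, temporal-spatial and
#' hand-rim variables, joint kinematics, and Newton-Euler joint kinetics,
#' all summarized over the selected cycles.
#'
#' @param markers a [marker_series()].
#' @param rim a [handrim_series()].
#' @param config a [study_config()].
#' @param anthro an [anthropometry()].
#' @param geometry a [wheelchair_geometry()].
#' @return An object of class `propulsion_analysis`.
#' @export
analyze_trial <- function(markers, rim, config = study_config(),
                          anthro = anthropometry(),
                          geometry = wheelchair_geometry()) {
  if (any(markers$gaps)) markers <- fill_gaps(markers)
  if (any(markers$gaps))
    stop("unfillable gaps remain; run reconstruct_markers() or trim the trial")
  rim_f <- rim
  rim_f$F <- lowpass_zero_phase(rim$F, rim$rate, config$filter$cutoff_hz,
                                config$filter$order)
  rim_f$M <- lowpass_zero_phase(rim$M, rim$rate, config$filter$cutoff_hz,
                                config$filter$order)
  ali <- synchronize(markers, rim_f, config$sync_target_rate)
  mkf <- ali$markers
  for (lab in mkf$labels)
    mkf$positions[, , lab] <- lowpass_zero_phase(
      mkf$positions[, , lab], mkf$rate,
      config$marker_filter$cutoff_hz, config$marker_filter$order)
  rate <- ali$common_rate
  pushes <- detect_pushes(ali$rim$M[, 3], config$event_threshold_nm, rate,
                          config$min_push_s)
  cycles <- segment_cycles(pushes, rate)
  cycles <- select_cycles(cycles, config$analysis_window, config$n_cycles)
  wc <- (marker_xyz(mkf, "ulr") + marker_xyz(mkf, "rdl")) / 2
  m3 <- marker_xyz(mkf, "3m")
  cycles <- lapply(cycles, locate_instants, hand_xyz = m3,
                   geometry = geometry, contact_xyz = wc)
  ts <- temporal_spatial(cycles, ali$rim, geometry, hand_xyz = wc)
  hr <- summarize_handrim_cycles(ali$rim, cycles)
  frames <- build_frames(mkf)
  ja <- joint_angles(frames)
  inertia <- segment_inertia(anthro)
  motion <- derive_motion(frames, inertia)
  jk <- inverse_dynamics(frames, motion, inertia, ali$rim, geometry)
  npts <- config$normalization_points
  kin_sum <- summarize_angles(ja, cycles, npts, ts)
  kinet_sum <- summarize_kinetics(jk, cycles, npts)
  structure(list(temporal_spatial = ts, handrim = hr,
                 kinematics = kin_sum, kinetics = kinet_sum,
                 cycles = cycles, joint_angles = ja, joint_kinetics = jk,
                 frames = frames, aligned = ali, config = config),
            class = "propulsion_analysis")
}

mean_normalized <- function(x, cycles, npts) {
  traces <- vapply(cycles, function(cy) normalize_cycle(x, cy, npts),
                   numeric(npts))
  rowMeans(traces)
}

phase_tag <- function(idx, npts, push_fraction) {
  if ((idx - 1) / (npts - 1) <= push_fraction) "p" else "r"
}

summarize_angles <- function(ja, cycles, npts, ts) {
  pf <- ts$Pphase / (ts$Pphase + ts$Rphase)
  out <- lapply(colnames(ja$angles), function(nm) {
    tr <- mean_normalized(ja$angles[, nm], cycles, npts)
    i_max <- which.max(tr); i_min <- which.min(tr)
    list(trace = tr, max = tr[i_max], min = tr[i_min],
         ROM = tr[i_max] - tr[i_min],
         phase_max = phase_tag(i_max, npts, pf),
         phase_min = phase_tag(i_min, npts, pf))
  })
  names(out) <- colnames(ja$angles)
  out
}

summarize_kinetics <- function(jk, cycles, npts) {
  inst_names <- c("HO", "TC", "HR", "FT", "AR")
  out <- lapply(c(wrist = "wrist", elbow = "elbow", shoulder = "shoulder"),
                function(j) {
    comp <- cbind(jk[[j]]$F, jk[[j]]$M)
    colnames(comp) <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")
    per_comp <- lapply(colnames(comp), function(nm) {
      tr <- mean_normalized(comp[, nm], cycles, npts)
      at_inst <- colMeans(do.call(rbind, lapply(cycles, function(cy) {
        idx <- c(cy$i_HO, cy$i_TC, cy$i_HR, cy$i_FT, cy$i_AR)
        ifelse(is.na(idx), NA_real_, comp[idx, nm])
      })))
      names(at_inst) <- inst_names
      list(trace = tr, max = max(tr), min = min(tr), at = at_inst)
    })
    names(per_comp) <- colnames(comp)
    per_comp
  })
  out
}

#' @export
print.propulsion_analysis <- function(x, ...) {
  cat("propulsion_analysis\n-------------------\n")
  print(x$temporal_spatial)
  print(x$handrim)
  cat("joint angle ROM (deg):\n")
  for (nm in names(x$kinematics))
    cat(sprintf("  %-9s %6.1f (max %7.1f %s, min %7.1f %s)\n", nm,
                x$kinematics[[nm]]$ROM, x$kinematics[[nm]]$max,
                x$kinematics[[nm]]$phase_max, x$kinematics[[nm]]$min,
                x$kinematics[[nm]]$phase_min))
  invisible(x)
}

#' Serialize an analysis to a JSON report
#'
#' Numeric values are written at full precision, so identical inputs (same
#' configuration and seed) give byte-identical reports.
#'
#' @param analysis a [analyze_trial()] result.
#' @param path output file; `NULL` returns the JSON string.
#' @param meta optional named list recorded under `meta` (e.g. seed).
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(analysis, path = NULL, meta = list()) {
  ts <- analysis$temporal_spatial
  hr <- analysis$handrim
  rep <- list(
    meta = meta,
    temporal_spatial = list(
      PF = ts$PF, Dist = ts$Dist, Pphase = ts$Pphase, Rphase = ts$Rphase,
      `Pphase/Rphase` = ts$ratio, CA = ts$CA, RA = ts$RA),
    handrim = list(
      Ftotmax = hr$Ftot_max, Ftangmax = hr$Ftang_max, Feff = hr$Feff,
      ERF = hr$ERF, Mtotmax = hr$Mtot_max, ERM = hr$ERM),
    kinematics = lapply(analysis$kinematics, function(a)
      list(max = a$max, min = a$min, ROM = a$ROM,
           phase_max = a$phase_max, phase_min = a$phase_min)),
    kinetics = lapply(analysis$kinetics, function(j)
      lapply(j, function(cmp)
        list(max = cmp$max, min = cmp$min, at = as.list(cmp$at)))))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
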