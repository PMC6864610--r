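# Data model and file I/O for marker and hand-rim streams.
#
# CSV dialect (both streams): first line "# rate=<Hz> [key=value ...]",
# second line a column header, then comma-separated numeric rows with "."
# as decimal mark.  Marker columns are t,<label>_x,<label>_y,<label>_z per
# label; hand-rim columns are t,Fx,Fy,Fz,Mx,My,Mz,theta.

#' Canonical marker labels of the reduced 15-marker upper-limb model
#'
#' Order is fixed: trunk (c7, acromia, humeral head), arm (reference cluster,
#' epicondyles), hand (styloids, metacarpals).  All marker containers in the
#' package store markers in this order.
#'
#' @return Character vector of the 15 labels.
#' @export
marker_labels <- function() {
  c("c7", "acrr", "acrl", "hha", "hhp",
    "rm1", "rm2", "rm3", "epc", "ipc",
    "ulr", "rdl", "2m", "3m", "5m")
}

#' Construct a marker frame series
#'
#' @param positions numeric array `[n_samples, 3, n_markers]` of lab-frame
#'   coordinates in metres (x forward, y to the left, z up).  `NA` entries are
#'   treated as gaps.
#' @param labels character vector of marker names, a subset of
#'   [marker_labels()].
#' @param rate sampling frequency in Hz.
#' @param gaps optional logical matrix `[n_samples, n_markers]`; derived from
#'   `NA` positions when missing.
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(positions, labels, rate, gaps = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number")
  labels <- as.character(labels)
  bad <- setdiff(labels, marker_labels())
  if (length(bad))
    stop("unknown marker label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are: ", paste(marker_labels(), collapse = ", "))
  if (anyDuplicated(labels)) stop("duplicated marker labels")
  positions <- as.array(positions)
  if (length(dim(positions)) != 3L || dim(positions)[2] != 3L)
    stop("positions must be an [n, 3, n_markers] array")
  if (dim(positions)[3] != length(labels))
    stop("positions third dimension must match number of labels")
  # canonical Table-ordering of labels
  ord <- order(match(labels, marker_labels()))
  labels <- labels[ord]
  positions <- positions[, , ord, drop = FALSE]
  dimnames(positions) <- list(NULL, c("x", "y", "z"), labels)
  if (is.null(gaps)) {
    gaps <- apply(is.na(positions), c(1, 3), any)
    gaps <- matrix(gaps, nrow = dim(positions)[1], ncol = length(labels),
                   dimnames = list(NULL, labels))
  } else {
    gaps <- as.matrix(gaps)[, ord, drop = FALSE]
    colnames(gaps) <- labels
  }
  ok <- positions[!is.na(positions)]
  if (length(ok) && any(!is.finite(ok)))
    stop("non-finite marker coordinate")
  structure(list(positions = positions, labels = labels, rate = rate,
                 gaps = gaps),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("marker_series: %d samples x %d markers @ %g Hz (%.2f s)\n",
              nrow(x$gaps), length(x$labels), x$rate, nrow(x$gaps) / x$rate))
  cat("  markers:", paste(x$labels, collapse = " "), "\n")
  ngap <- sum(x$gaps)
  if (ngap) cat(sprintf("  gaps: %d flagged marker-samples\n", ngap))
  invisible(x)
}

n_samples <- function(x) UseMethod("n_samples")
#' @export
n_samples.marker_series <- function(x) dim(x$positions)[1]
#' @export
n_samples.handrim_series <- function(x) length(x$theta)

#' Extract one marker trajectory as an n x 3 matrix
#' @param series a `marker_series`
#' @param label marker name
#' @return numeric matrix `[n, 3]`.
#' @export
marker_xyz <- function(series, label) {
  if (!label %in% series$labels) stop("marker not present: ", label)
  series$positions[, , label, drop = TRUE]
}

#' Construct a hand-rim kinetic series
#'
#' Forces and moments are expressed in the wheel-plane sensor frame
#' (X backward, Y up, Z along the axle pointing inboard); `theta` is the
#' unwrapped wheel angle in radians, increasing with forward rotation.
#'
#' @param F numeric matrix `[n, 3]`, N.
#' @param M numeric matrix `[n, 3]`, Nm.
#' @param theta numeric vector, rad (will be unwrapped if wrapped).
#' @param rate sampling frequency, Hz.
#' @param side `"left"` or `"right"`.
#' @return An object of class `handrim_series`.
#' @export
handrim_series <- function(F, M, theta, rate, side = c("right", "left")) {
  side <- match.arg(side)
  F <- as.matrix(F); M <- as.matrix(M); theta <- as.numeric(theta)
  if (ncol(F) != 3L || ncol(M) != 3L) stop("F and M must have 3 columns")
  n <- length(theta)
  if (nrow(F) != n || nrow(M) != n)
    stop("F, M and theta must have the same length")
  if (n == 0L) stop("no samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  colnames(F) <- c("x", "y", "z"); colnames(M) <- c("x", "y", "z")
  structure(list(F = F, M = M, theta = unwrap_angle(theta), rate = rate,
                 side = side),
            class = "handrim_series")
}

#' @export
print.handrim_series <- function(x, ...) {
  cat(sprintf("handrim_series (%s): %d samples @ %g Hz (%.2f s)\n",
              x$side, length(x$theta), x$rate, length(x$theta) / x$rate))
  cat(sprintf("  wheel rotation: %.2f rad\n",
              x$theta[length(x$theta)] - x$theta[1]))
  invisible(x)
}

#' Unwrap a wrapped angle signal to a continuous one
#'
#' Jumps larger than pi between consecutive samples are removed by adding the
#' appropriate multiple of 2*pi.
#'
#' @param theta numeric vector, rad.
#' @return continuous angle vector.
#' @export
unwrap_angle <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  corr <- -2 * pi * round(d / (2 * pi))
  theta + c(0, cumsum(ifelse(abs(d) > pi, corr, 0)))
}

parse_header_line <- function(line) {
  if (!startsWith(line, "#")) stop("missing '# key=value' header line")
  toks <- strsplit(trimws(sub("^#", "", line)), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) == 2) p[2] else NA_character_,
                 character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

#' Read a marker trajectory CSV
#'
#' @param path file path.
#' @param dialect only `"csv"` is supported.
#' @return A [marker_series()]; blank cells become gap flags.
#' @export
read_marker_series <- function(path, dialect = "csv") {
  if (!identical(dialect, "csv"))
    stop("unsupported dialect: ", dialect, " (only 'csv' is implemented)")
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- parse_header_line(readLines(path, n = 1L))
  if (is.na(hdr["rate"])) stop("missing rate in header of ", path)
  rate <- as.numeric(hdr[["rate"]])
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path)
  cn <- colnames(df)
  if (cn[1] != "t") stop("first column must be 't'")
  coord_cols <- cn[-1]
  m <- regmatches(coord_cols, regexec("^(.*)_([xyz])$", coord_cols))
  bad <- coord_cols[vapply(m, length, integer(1)) == 0]
  if (length(bad)) stop("malformed column name(s): ", paste(bad, collapse = ", "))
  labs <- unique(vapply(m, `[`, character(1), 2))
  unknown <- setdiff(labs, marker_labels())
  if (length(unknown))
    stop("unknown marker label(s): ", paste(unknown, collapse = ", "),
         "; allowed labels are: ", paste(marker_labels(), collapse = ", "))
  n <- nrow(df)
  pos <- array(NA_real_, c(n, 3, length(labs)),
               dimnames = list(NULL, c("x", "y", "z"), labs))
  for (lab in labs)
    for (ax in c("x", "y", "z")) {
      col <- paste0(lab, "_", ax)
      if (!col %in% cn) stop("missing column: ", col)
      pos[, ax, lab] <- as.numeric(df[[col]])
    }
  marker_series(pos, labs, rate)
}

#' Write a marker trajectory CSV
#' @param series a `marker_series`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_marker_series <- function(series, path) {
  n <- n_samples(series)
  t <- (seq_len(n) - 1L) / series$rate
  cols <- list(t = t)
  for (lab in series$labels)
    for (ax in c("x", "y", "z"))
      cols[[paste0(lab, "_", ax)]] <- series$positions[, ax, lab]
  lines <- c(sprintf("# rate=%.10g", series$rate),
             paste(names(cols), collapse = ","),
             do.call(paste, c(lapply(cols, fmt_num), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- ""
  out
}

#' Read a hand-rim kinetic CSV
#'
#' Expects columns t,Fx,Fy,Fz,Mx,My,Mz,theta; theta is unwrapped on read.
#'
#' @param path file path.
#' @param side `"left"` or `"right"`.
#' @return A [handrim_series()].
#' @export
read_handrim_series <- function(path, side = c("right", "left")) {
  side <- match.arg(side)
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- parse_header_line(readLines(path, n = 1L))
  if (is.na(hdr["rate"])) stop("missing rate in header of ", path)
  rate <- as.numeric(hdr[["rate"]])
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path)
  need <- c("t", "Fx", "Fy", "Fz", "Mx", "My", "Mz", "theta")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  t <- df$t
  if (any(diff(t) <= 0)) stop("non-monotone time column in ", path)
  handrim_series(F = cbind(df$Fx, df$Fy, df$Fz),
                 M = cbind(df$Mx, df$My, df$Mz),
                 theta = df$theta, rate = rate, side = side)
}

#' Write a hand-rim kinetic CSV
#' @param series a `handrim_series`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_handrim_series <- function(series, path) {
  n <- n_samples(series)
  t <- (seq_len(n) - 1L) / series$rate
  lines <- c(sprintf("# rate=%.10g side=%s", series$rate, series$side),
             "t,Fx,Fy,Fz,Mx,My,Mz,theta",
             paste(fmt_num(t),
                   fmt_num(series$F[, 1]), fmt_num(series$F[, 2]),
                   fmt_num(series$F[, 3]),
                   fmt_num(series$M[, 1]), fmt_num(series$M[, 2]),
                   fmt_num(series$M[, 3]),
                   fmt_num(series$theta), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Subject anthropometry
#'
#' Segment geometry models the arm, forearm and hand as solids of revolution
#' (frusta) with the given proximal/distal radii.  Segment masses default to
#' standard body-mass fractions (arm 2.8%, forearm 1.6%, hand 0.6%).
#'
#' @param body_mass kg.
#' @param height m.
#' @param segments optional list with elements `arm`, `forearm`, `hand`, each
#'   a list `(mass, length, r_prox, r_dist, com_fraction)`; defaults are
#'   derived from `body_mass` and `height`.
#' @return An object of class `anthropometry`.
#' @export
anthropometry <- function(body_mass = 72.1, height = 1.76, segments = NULL) {
  if (body_mass <= 0 || height <= 0) stop("body_mass and height must be positive")
  if (is.null(segments)) {
    segments <- list(
      arm     = list(mass = 0.028 * body_mass, length = 0.172 * height,
                     r_prox = 0.045, r_dist = 0.035, com_fraction = 0.436),
      forearm = list(mass = 0.016 * body_mass, length = 0.157 * height,
                     r_prox = 0.035, r_dist = 0.025, com_fraction = 0.430),
      hand    = list(mass = 0.006 * body_mass, length = 0.108 * height,
                     r_prox = 0.035, r_dist = 0.025, com_fraction = 0.506))
  }
  for (nm in c("arm", "forearm", "hand")) {
    s <- segments[[nm]]
    if (is.null(s)) stop("missing segment: ", nm)
    vals <- unlist(s[c("mass", "length", "r_prox", "r_dist", "com_fraction")])
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("segment ", nm, " parameters must be positive")
    if (s$mass >= body_mass) stop("segment mass exceeds body mass")
  }
  structure(list(body_mass = body_mass, height = height, segments = segments),
            class = "anthropometry")
}

#' Wheelchair geometry
#'
#' @param wheel_diameter m (default 0.600).
#' @param rim_radius hand-rim radius, m (default 0.260).
#' @param camber wheel camber, degrees.
#' @param axle_position lab-frame position of the wheel hub, m; defaults to
#'   `c(0, -0.25, wheel_diameter / 2)` (right wheel of a chair centred on the
#'   lab origin).
#' @param seat named numeric vector of seat dimensions, m (descriptive only).
#' @return An object of class `wheelchair_geometry`.
#' @export
wheelchair_geometry <- function(wheel_diameter = 0.600, rim_radius = 0.260,
                                camber = 0, axle_position = NULL,
                                seat = NULL) {
  if (wheel_diameter <= 0) stop("wheel_diameter must be positive")
  if (rim_radius <= 0 || rim_radius >= wheel_diameter / 2 + 0.05)
    stop("rim_radius must lie in (0, wheel_diameter/2 + 0.05)")
  if (is.null(axle_position))
    axle_position <- c(0, -0.25, wheel_diameter / 2)
  if (length(axle_position) != 3L)
    stop("axle_position must be a 3-vector")
  structure(list(wheel_diameter = wheel_diameter, rim_radius = rim_radius,
                 camber = camber, axle_position = axle_position, seat = seat),
            class = "wheelchair_geometry")
}

#' Default study configuration
#'
#' Defaults reproduce the protocol conditions: treadmill at 0.833 m/s, kinetic
#' low-pass at 20 Hz (4th-order Butterworth, zero phase), push detection at
#' 1 Nm on the axle moment, five consecutive cycles, 101-point normalization.
#'
#' @param ... overrides for any configuration key.
#' @return An object of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    treadmill_speed = 0.833,
    analysis_window = c(0, Inf),
    n_cycles = 5L,
    filter = list(order = 4L, cutoff_hz = 20),
    marker_filter = list(order = 4L, cutoff_hz = 6),
    event_threshold_nm = 1.0,
    min_push_s = 0.1,
    normalization_points = 101L,
    angle_reference = "backward_horizontal",
    sync_target_rate = 240)
  over <- list(...)
  for (k in names(over)) {
    if (!k %in% names(cfg)) stop("unknown configuration key: ", k)
    if (is.list(cfg[[k]]) && is.list(over[[k]]))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    else cfg[[k]] <- over[[k]]
  }
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

validate_config <- function(cfg) {
  if (cfg$treadmill_speed <= 0) stop("treadmill_speed must be > 0")
  w <- cfg$analysis_window
  if (length(w) != 2L || w[1] >= w[2])
    stop("analysis_window must satisfy start < end")
  if (cfg$n_cycles < 1) stop("n_cycles must be >= 1")
  if (cfg$filter$cutoff_hz <= 0 || cfg$filter$order < 1)
    stop("filter must have positive cutoff_hz and order >= 1")
  if (cfg$event_threshold_nm <= 0) stop("event_threshold_nm must be > 0")
  if (cfg$normalization_points < 2) stop("normalization_points must be >= 2")
  invisible(cfg)
}

#' Load a study configuration from a YAML file
#'
#' Unspecified keys take the protocol defaults of [study_config()]; an empty
#' file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if ("n_cycles" %in% names(vals) && vals$n_cycles < 1)
    stop("n_cycles must be >= 1 (got ", vals$n_cycles, ")")
  do.call(study_config, vals)
}
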