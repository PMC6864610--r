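# Independent reference implementations used as oracles.  These deliberately
# avoid the package's vectorized code paths.

# per-sample state-machine threshold scan for push detection
oracle_push_scan <- function(m, thr, rate, min_push_s = 0) {
  on <- integer(0); off <- integer(0)
  in_push <- FALSE; i_start <- NA_integer_
  for (i in seq_along(m)) {
    if (!in_push) {
      if (i > 1 && m[i] > thr && m[i - 1] <= thr) {
        in_push <- TRUE; i_start <- i
      }
    } else {
      if (m[i] <= thr && m[i - 1] > thr) {
        in_push <- FALSE
        if ((i - i_start) / rate >= min_push_s) {
          on <- c(on, i_start); off <- c(off, i)
        }
      }
    }
  }
  cbind(i_on = on, i_off = off)
}

# brute-force angle unwrap: add/subtract 2*pi at every backward/forward jump
oracle_unwrap <- function(th) {
  out <- th
  offset <- 0
  for (i in seq_along(th)[-1]) {
    d <- th[i] - th[i - 1]
    if (d < -pi) offset <- offset + 2 * pi
    if (d > pi) offset <- offset - 2 * pi
    out[i] <- th[i] + offset
  }
  out
}

# exact rank-sum two-sided p by full enumeration of group assignments
oracle_ranksum_exact <- function(x, y) {
  n_x <- length(x); n <- n_x + length(y)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n_x * (n_x + 1) / 2
  u_obs <- u_of(seq_len(n_x))
  all_u <- apply(utils::combn(n, n_x), 2, u_of)
  mean(abs(all_u - n_x * length(y) / 2) >= abs(u_obs - n_x * length(y) / 2) - 1e-9)
}

# hand-written static joint loads under gravity plus an optional hand load
oracle_static_loads <- function(coms, joints, masses, F_ext = c(0, 0, 0),
                                p_ext = c(0, 0, 0), g = c(0, 0, -9.81)) {
  # coms/joints: lists hand/forearm/arm -> 3-vectors; joints = wrist/elbow/gh
  W <- list()
  segs <- c("hand", "forearm", "arm")
  jns <- c("wrist", "elbow", "shoulder")
  for (k in 1:3) {
    lower <- segs[seq_len(k)]
    Fj <- -Reduce(`+`, lapply(lower, function(s) masses[[s]] * g)) - F_ext
    Mj <- Reduce(`+`, lapply(lower, function(s)
      cross_v(joints[[k]] - coms[[s]], masses[[s]] * g)))
    Mj <- Mj - cross_v(p_ext - joints[[k]], F_ext)
    W[[jns[k]]] <- list(F = Fj, M = Mj)
  }
  W
}

cross_v <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
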