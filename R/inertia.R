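# Segment inertial parameters from solids of revolution.

GRAVITY <- c(0, 0, -9.81)

# Simpson integration of f over [0, 1] with an odd number of nodes.
simpson01 <- function(f, n_nodes = 2001L) {
  s <- seq(0, 1, length.out = n_nodes)
  w <- c(1, rep(c(4, 2), length.out = n_nodes - 2L), 1)
  w[n_nodes - 1L] <- 4
  h <- 1 / (n_nodes - 1L)
  sum(w * f(s)) * h / 3
}

frustum_inertia <- function(mass, length, r_prox, r_dist) {
  # homogeneous frustum of revolution, longitudinal axis = local y
  r_of <- function(s) r_prox + (r_dist - r_prox) * s
  vol <- simpson01(function(s) pi * r_of(s)^2) * length
  rho <- mass / vol
  zbar <- simpson01(function(s) pi * r_of(s)^2 * s) * length^2 * rho / mass
  I_ax <- simpson01(function(s) pi * r_of(s)^4 / 2) * length * rho
  I_tr <- simpson01(function(s)
    pi * r_of(s)^2 * (r_of(s)^2 / 4 + (s * length - zbar)^2)) * length * rho
  list(com_fraction = zbar / length,
       I_local = diag(c(I_tr, I_ax, I_tr)))
}

#' Segment inertial parameters
#'
#' Mass, COM fraction along the longitudinal axis (from the proximal joint)
#' and the inertia tensor at the COM in the segment frame (y longitudinal),
#' computed from homogeneous frusta of revolution with the anthropometric
#' radii and lengths.  The COM fraction of the anthropometry table overrides
#' the geometric one (the frustum sets only the gyration radii).
#'
#' @param anthro an [anthropometry()].
#' @return list per segment (`arm`, `forearm`, `hand`) with `mass`, `length`,
#'   `com_fraction` and `I_local` (3x3, kg m^2).
#' @export
segment_inertia <- function(anthro) {
  out <- lapply(c(arm = "arm", forearm = "forearm", hand = "hand"),
                function(nm) {
    s <- anthro$segments[[nm]]
    fi <- frustum_inertia(s$mass, s$length, s$r_prox, s$r_dist)
    ev <- diag(fi$I_local)
    if (any(ev <= 0)) stop("unphysical inertia for segment ", nm)
    list(mass = s$mass, length = s$length,
         com_fraction = s$com_fraction, I_local = fi$I_local)
  })
  structure(out, class = "segment_inertia")
}

#' @export
print.segment_inertia <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-8s m=%.3f kg  L=%.3f m  com=%.2f  Iax=%.2e kg m^2\n",
                nm, x[[nm]]$mass, x[[nm]]$length, x[[nm]]$com_fraction,
                x[[nm]]$I_local[2, 2]))
  invisible(x)
}
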