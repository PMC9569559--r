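#' Chemotactic potential from the temporal VEGFA derivative
#'
#' The potential \eqn{f = -\beta\,c_t} wherever the concentration is rising
#' (\eqn{c_t > 0}) and \eqn{f = 0} wherever it is falling or flat. The
#' transport velocity of sprout tips is its gradient, \eqn{v_m = \nabla f}:
#' because \eqn{c_t} is *smaller* near the patch (the spatial factor grows
#' with distance), \eqn{f} is *less negative* there and the gradient points
#' patch-ward during growth periods. During rest periods the potential -- and
#' with it the drift -- vanishes identically and tips move by pure random
#' motility.
#'
#' The potential is evaluated analytically (the field is closed-form), never
#' by differencing the concentration in time.
#'
#' @inheritParams vegf_concentration
#' @param beta chemotactic strength \eqn{\beta} (dimensionless, default 1).
#' @return Numeric vector of potential values, all <= 0.
#' @examples
#' chemotactic_potential(c(1, 0.5), 0, vegf_params())   # -0.379 (rising VEGFA)
#' chemotactic_potential(c(1, 0.5), 3, vegf_params())   # 0 (rest period)
#' @export
chemotactic_potential <- function(point, t, params = vegf_params(), beta = 1) {
  ct <- vegf_concentration_rate(point, t, params)
  ifelse(ct > 0, -beta * ct, 0)
}

#' Chemotactic potential sampled on the sub-lattice
#'
#' Evaluates [chemotactic_potential()] at every corner of the sub-lattice at
#' time `t`, as the `(N+1) x (N+1)` matrix consumed by
#' [velocity_on_main_lattice()].
#'
#' @param lattice a [dual_lattice()].
#' @inheritParams chemotactic_potential
#' @return `(N+1) x (N+1)` matrix (rows: x index, columns: y index).
#' @export
potential_grid <- function(lattice, t, params = vegf_params(), beta = 1) {
  xs <- lattice$x_sub
  rp <- sqrt(outer((xs - params$patch_center[1])^2,
                   (xs - params$patch_center[2])^2, "+"))
  ct <- vegf_time_factor_rate(t, params) * .spatial_factor(rp, params)
  ifelse(ct > 0, -beta * ct, 0)
}

#' Transport velocity on the main lattice
#'
#' Discrete gradient of the potential: each main-lattice (cell-center)
#' component averages the two adjacent difference quotients of the potential
#' at the surrounding sub-lattice corners,
#' \deqn{(v_m)_{i,j,1} = \frac{1}{2}\left(\frac{f_{i,j}-f_{i-1,j}}{h} +
#'       \frac{f_{i,j-1}-f_{i-1,j-1}}{h}\right)}
#' and analogously in y. The stencil is exact for potentials linear in the
#' coordinates. The chemotactic strength \eqn{\beta} enters once, inside the
#' potential, so this operator is the plain averaged difference quotient.
#'
#' @param f_sub potential on the full sub-lattice: `(N+1) x (N+1)` matrix.
#' @param h grid spacing `1/N`.
#' @return List with `vx` and `vy`, each an `N x N` matrix on the main
#'   lattice.
#' @export
velocity_on_main_lattice <- function(f_sub, h) {
  stopifnot(is.matrix(f_sub), nrow(f_sub) == ncol(f_sub))
  N <- nrow(f_sub) - 1L
  if (N < 1L || abs(h * N - 1) > 1e-9) {
    stop("sub-lattice shape ", nrow(f_sub), "x", ncol(f_sub),
         " inconsistent with h = ", h, " (expect (1/h + 1) per side)")
  }
  hi <- 2:(N + 1L)
  lo <- 1:N
  vx <- ((f_sub[hi, hi] - f_sub[lo, hi]) + (f_sub[hi, lo] - f_sub[lo, lo])) / (2 * h)
  vy <- ((f_sub[hi, hi] - f_sub[hi, lo]) + (f_sub[lo, hi] - f_sub[lo, lo])) / (2 * h)
  list(vx = vx, vy = vy)
}

#' Upwind splitting of a velocity component
#'
#' \eqn{v^+ = \max(0, v)}, \eqn{v^- = \max(0, -v)}: both parts are
#' nonnegative, `pos - neg` reconstructs `v` exactly, and `pos * neg = 0`.
#' Advected mass only flows downwind of each part, which is what preserves
#' positivity in the scheme.
#'
#' @param v numeric vector/matrix velocity component.
#' @return List with `pos` and `neg`, same shape as `v`.
#' @export
upwind_split <- function(v) {
  list(pos = pmax(v, 0), neg = pmax(-v, 0))
}

#' Upwind-split velocity field
#'
#' Applies [upwind_split()] to both components of a velocity field on the
#' main lattice, the form consumed by the flux and transition-probability
#' operators.
#'
#' @param velocity list with `vx`, `vy` (from [velocity_on_main_lattice()]).
#' @return Object of class `velocity_split`: list with `vx_pos`, `vx_neg`,
#'   `vy_pos`, `vy_neg` and the scalar `vhat` (max over all sites and split
#'   components, the speed entering the stability bound).
#' @export
velocity_split <- function(velocity) {
  stopifnot(is.list(velocity), !is.null(velocity$vx), !is.null(velocity$vy))
  if (!identical(dim(velocity$vx), dim(velocity$vy))) {
    stop("vx and vy shapes differ")
  }
  sx <- upwind_split(velocity$vx)
  sy <- upwind_split(velocity$vy)
  structure(list(vx_pos = sx$pos, vx_neg = sx$neg,
                 vy_pos = sy$pos, vy_neg = sy$neg,
                 vhat = max(sx$pos, sx$neg, sy$pos, sy$neg)),
            class = "velocity_split")
}

# zero split field on an N x N main lattice (rest periods)
.zero_split <- function(N) {
  z <- matrix(0, N, N)
  structure(list(vx_pos = z, vx_neg = z, vy_pos = z, vy_neg = z, vhat = 0),
            class = "velocity_split")
}
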