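#' Upwind advective flux on the sub-lattice faces
#'
#' The advective (transport) part of the flux, assembled upwind so that mass
#' leaves a cell only in the direction its velocity points:
#' \deqn{G_{i,j,1} = n_{i,j}(v_m)^+_{i,j,1} - n_{i+1,j}(v_m)^-_{i+1,j,1}}
#' on the face between cells `i` and `i+1` (and analogously in y). Faces on
#' the domain boundary carry zero advective flux (zero-flux walls).
#'
#' Face-array convention: `Gx` is `(N+1) x N`; its row `r` is the x-face with
#' index `i = r - 1` (`i = 0..N`), so rows 1 and N+1 are the walls. `Gy` is
#' the transpose arrangement, `N x (N+1)`.
#'
#' @param n `N x N` density matrix on the main lattice (nonnegative).
#' @param split a [velocity_split()] with `N x N` components.
#' @return List with face matrices `Gx` (`(N+1) x N`) and `Gy` (`N x (N+1)`).
#' @export
advective_flux <- function(n, split) {
  stopifnot(is.matrix(n), inherits(split, "velocity_split"))
  N <- nrow(n)
  if (!identical(dim(n), dim(split$vx_pos))) {
    stop("density and velocity shapes differ")
  }
  Gx <- matrix(0, N + 1L, N)
  Gy <- matrix(0, N, N + 1L)
  if (N > 1L) {
    i <- 1:(N - 1L)
    Gx[i + 1L, ] <- n[i, ] * split$vx_pos[i, ] - n[i + 1L, ] * split$vx_neg[i + 1L, ]
    Gy[, i + 1L] <- n[, i] * split$vy_pos[, i] - n[, i + 1L] * split$vy_neg[, i + 1L]
  }
  list(Gx = Gx, Gy = Gy)
}

#' Total flux with zero-flux boundary closure
#'
#' Diffusive difference quotient plus the advective flux on interior faces,
#' \deqn{F_{i,j,1} = -d\,\frac{n_{i+1,j} - n_{i,j}}{h} + G_{i,j,1},}
#' with every domain-boundary face exactly zero (no mass crosses the walls).
#'
#' @inheritParams advective_flux
#' @param G advective flux from [advective_flux()].
#' @param d random motility coefficient, >= 0.
#' @param h grid spacing.
#' @return List with face matrices `Fx`, `Fy` (same shapes as in `G`).
#' @export
total_flux <- function(n, G, d, h) {
  stopifnot(is.matrix(n), d >= 0, h > 0)
  N <- nrow(n)
  Fx <- matrix(0, N + 1L, N)
  Fy <- matrix(0, N, N + 1L)
  if (N > 1L) {
    i <- 1:(N - 1L)
    Fx[i + 1L, ] <- -d * (n[i + 1L, ] - n[i, ]) / h + G$Gx[i + 1L, ]
    Fy[, i + 1L] <- -d * (n[, i + 1L] - n[, i]) / h + G$Gy[, i + 1L]
  }
  list(Fx = Fx, Fy = Fy)
}

#' Stable time increment for the explicit scheme
#'
#' The scheme keeps every stencil weight nonnegative (and hence the density
#' nonnegative) when
#' \deqn{\tau_k \le \frac{h^2}{4\,(d + h\,\hat v_k)},}
#' where \eqn{\hat v_k} is the maximum over all sites and components of the
#' upwind-split velocities. The returned step is that bound scaled by a
#' `safety` factor in (0, 1]; the default 0.9 keeps the stay probability
#' strictly positive at every site.
#'
#' @param d random motility coefficient, >= 0.
#' @param h grid spacing.
#' @param split a [velocity_split()], or a single nonnegative number taken as
#'   \eqn{\hat v_k} directly.
#' @param safety factor in (0, 1].
#' @return The time increment \eqn{\tau_k} (days).
#' @examples
#' stable_timestep(d = 0.0001728, h = 0.01, split = 0)  # 0.9 * 0.14468
#' @export
stable_timestep <- function(d, h, split = 0, safety = 0.9) {
  stopifnot(d >= 0, h > 0, safety > 0, safety <= 1)
  vhat <- if (inherits(split, "velocity_split")) split$vhat else as.numeric(split)
  stopifnot(length(vhat) == 1L, vhat >= 0)
  if (d == 0 && vhat == 0) {
    stop("stable_timestep(): d = 0 and vhat = 0 give no dynamics")
  }
  safety * h^2 / (4 * (d + h * vhat))
}

#' Per-site transition probabilities of the hybrid scheme
#'
#' The probabilistic reading of the upwind stencil: at each main-lattice site
#' the 5-tuple (stay, left, right, down, up) with
#' \deqn{P^0 = 1 - \frac{4 d \tau}{h^2} - \frac{\tau}{h}\,
#'   (v^+_x + v^-_x + v^+_y + v^-_y),\qquad
#'   P^{move} = \frac{d\tau}{h^2} + \frac{\tau}{h}\,v^{(dir)},}
#' where the move in each direction carries that direction's split component
#' (left uses \eqn{v^-_x}, right \eqn{v^+_x}, down \eqn{v^-_y}, up
#' \eqn{v^+_y}). At wall-adjacent sites the wall-facing move is redirected
#' into "stay" (reflecting closure), the exact probabilistic counterpart of
#' the zero-flux boundary condition. Under the [stable_timestep()] bound all
#' entries are nonnegative and each site's tuple sums to 1.
#'
#' @inheritParams advective_flux
#' @param d random motility coefficient, >= 0.
#' @param h grid spacing.
#' @param tau time increment; must satisfy the stability bound
#'   (otherwise the stay weight can go negative and the call fails).
#' @return Object of class `transition_probabilities`: list of `N x N`
#'   matrices `stay`, `left`, `right`, `down`, `up`, plus `d`, `h`, `tau`.
#' @export
transition_probabilities <- function(split, d, h, tau) {
  stopifnot(inherits(split, "velocity_split"), d >= 0, h > 0, tau > 0)
  bound <- h^2 / (4 * (d + h * split$vhat))
  if (tau > bound * (1 + 1e-12)) {
    stop(sprintf(paste0("transition_probabilities(): tau = %g violates the ",
                        "stability bound %g (probabilities would go negative)"),
                 tau, bound))
  }
  N <- nrow(split$vx_pos)
  pdif <- d * tau / h^2
  adv <- tau / h
  left  <- pdif + adv * split$vx_neg
  right <- pdif + adv * split$vx_pos
  down  <- pdif + adv * split$vy_neg
  up    <- pdif + adv * split$vy_pos
  stay  <- 1 - (left + right + down + up)
  # reflecting closure: wall-facing moves fold into stay
  stay[1, ] <- stay[1, ] + left[1, ];  left[1, ]  <- 0
  stay[N, ] <- stay[N, ] + right[N, ]; right[N, ] <- 0
  stay[, 1] <- stay[, 1] + down[, 1];  down[, 1]  <- 0
  stay[, N] <- stay[, N] + up[, N];    up[, N]    <- 0
  structure(list(stay = stay, left = left, right = right,
                 down = down, up = up, d = d, h = h, tau = tau),
            class = "transition_probabilities")
}

#' One continuum density update
#'
#' `density_step()` advances the sprout-tip density by the five-point
#' probability stencil
#' \deqn{n^{k+1}_{i,j} = n_{i,j}P^0_{i,j} + n_{i+1,j}P^{left}_{i+1,j}
#'  + n_{i-1,j}P^{right}_{i-1,j} + n_{i,j+1}P^{down}_{i,j+1}
#'  + n_{i,j-1}P^{up}_{i,j-1}.}
#' `density_step_flux()` advances it through the conservative flux form
#' (assemble the upwind advective flux, add diffusion, close the boundary,
#' take the discrete divergence). The two are algebraically identical and are
#' kept as independent code paths so each can serve as the other's oracle.
#' Both preserve nonnegativity (under the stability bound) and total mass
#' \eqn{\sum n h^2} exactly.
#'
#' @param n `N x N` nonnegative density matrix.
#' @param probs a [transition_probabilities()] object.
#' @return The updated `N x N` density matrix.
#' @export
density_step <- function(n, probs) {
  stopifnot(is.matrix(n), inherits(probs, "transition_probabilities"),
            identical(dim(n), dim(probs$stay)))
  N <- nrow(n)
  out <- n * probs$stay
  if (N > 1L) {
    i <- 1:(N - 1L)
    # from the right neighbor moving left, and the left neighbor moving right
    out[i, ]      <- out[i, ]      + n[i + 1L, ] * probs$left[i + 1L, ]
    out[i + 1L, ] <- out[i + 1L, ] + n[i, ]      * probs$right[i, ]
    # from the upper neighbor moving down, and the lower neighbor moving up
    out[, i]      <- out[, i]      + n[, i + 1L] * probs$down[, i + 1L]
    out[, i + 1L] <- out[, i + 1L] + n[, i]      * probs$up[, i]
  }
  out
}

#' @rdname density_step
#' @inheritParams advective_flux
#' @inheritParams transition_probabilities
#' @export
density_step_flux <- function(n, split, d, h, tau) {
  G <- advective_flux(n, split)
  Fl <- total_flux(n, G, d, h)
  N <- nrow(n)
  r <- 1:N
  div <- (Fl$Fx[r + 1L, , drop = FALSE] - Fl$Fx[r, , drop = FALSE]) / h +
         (Fl$Fy[, r + 1L, drop = FALSE] - Fl$Fy[, r, drop = FALSE]) / h
  n - tau * div
}
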