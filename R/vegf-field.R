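#' Parameters of the VEGFA concentration field
#'
#' Constants of the prescribed VEGFA distribution
#' \deqn{c(x, t) = a\,\{b + \sin(2\pi\sigma t)\,e^{-\gamma t}\}\,
#'       \{1 - (r_0 - r_p)^2/\epsilon^2\}}
#' for \eqn{r_p > R} and \eqn{c = 0} for \eqn{r_p \le R}, where \eqn{r_p} is
#' the distance from the patch center and \eqn{R} the patch radius. Time is
#' measured in days (one dimensionless time unit = one day).
#'
#' The defaults are the dimensionless simulation values (`a = 1`, `b = 0.39`,
#' `sigma = 0.23/2`, `gamma = 0.15`, `epsilon = 2.9`). When fitting measured
#' concentrations, `a` carries pg/mL units and absorbs the spatial factor at
#' the measurement location.
#'
#' With `epsilon = r0 - patch_radius` (the default 2.9 = 3 - 0.1) the spatial
#' factor vanishes exactly at the patch boundary, so the concentration is
#' continuous there.
#'
#' @param a amplitude (dimensionless, or pg/mL when fitted).
#' @param b baseline offset of the kinetic factor (dimensionless).
#' @param sigma oscillation frequency \eqn{\sigma} (cycles/day); must be > 0.
#' @param gamma exponential decay rate \eqn{\gamma} (1/day); must be >= 0.
#' @param epsilon spatial-shape constant \eqn{\epsilon} (dimensionless length).
#' @param r0 spatial offset constant (dimensionless length; the literal 3 of
#'   the concentration formula, exposed as a parameter).
#' @param patch_center numeric length-2, patch center \eqn{(x_p, y_p)}.
#' @param patch_radius patch radius \eqn{R} (dimensionless); must be > 0.
#' @return An object of class `vegf_params`.
#' @examples
#' p <- vegf_params()
#' vegf_concentration(c(1, 0.5), t = 0, p)
#' @export
vegf_params <- function(a = 1, b = 0.39, sigma = 0.23 / 2, gamma = 0.15,
                        epsilon = 2.9, r0 = 3,
                        patch_center = c(0, 0.5), patch_radius = 0.1) {
  stopifnot(is.numeric(a), length(a) == 1L,
            is.numeric(b), length(b) == 1L,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(r0), length(r0) == 1L,
            is.numeric(patch_center), length(patch_center) == 2L,
            is.numeric(patch_radius), length(patch_radius) == 1L,
            patch_radius > 0)
  structure(list(a = a, b = b, sigma = sigma, gamma = gamma,
                 epsilon = epsilon, r0 = r0,
                 patch_center = as.numeric(patch_center),
                 patch_radius = patch_radius),
            class = "vegf_params")
}

#' @export
print.vegf_params <- function(x, ...) {
  cat("VEGFA field parameters\n")
  cat(sprintf("  kinetic : a = %g, b = %g, sigma = %g /day, gamma = %g /day\n",
              x$a, x$b, x$sigma, x$gamma))
  cat(sprintf("  spatial : epsilon = %g, r0 = %g, patch center (%g, %g), radius %g\n",
              x$epsilon, x$r0, x$patch_center[1], x$patch_center[2],
              x$patch_radius))
  invisible(x)
}

# coerce points to an n x 2 matrix
.as_points <- function(point) {
  if (is.null(dim(point))) {
    stopifnot(length(point) == 2L)
    matrix(as.numeric(point), nrow = 1L)
  } else {
    stopifnot(ncol(point) == 2L)
    as.matrix(point)
  }
}

#' Distance from a point to the patch center
#'
#' Euclidean distance \eqn{r_p} from a position in the unit square to the
#' patch center.
#'
#' @param point numeric length-2 position, or an n x 2 matrix of positions.
#' @param params a [vegf_params()] object.
#' @return Nonnegative numeric vector of distances.
#' @export
distance_to_patch <- function(point, params = vegf_params()) {
  pts <- .as_points(point)
  sqrt((pts[, 1] - params$patch_center[1])^2 +
       (pts[, 2] - params$patch_center[2])^2)
}

#' Kinetic (temporal) factor of the VEGFA field and its time derivative
#'
#' `vegf_time_factor()` evaluates \eqn{a\{b + \sin(2\pi\sigma t)e^{-\gamma t}\}};
#' `vegf_time_factor_rate()` its analytic derivative
#' \eqn{a\,e^{-\gamma t}\{2\pi\sigma\cos(2\pi\sigma t) - \gamma\sin(2\pi\sigma t)\}}.
#'
#' @param t time in days (vectorized).
#' @param params a [vegf_params()] object.
#' @return Numeric vector the length of `t`.
#' @export
vegf_time_factor <- function(t, params = vegf_params()) {
  params$a * (params$b + sin(2 * pi * params$sigma * t) * exp(-params$gamma * t))
}

#' @rdname vegf_time_factor
#' @export
vegf_time_factor_rate <- function(t, params = vegf_params()) {
  w <- 2 * pi * params$sigma
  params$a * exp(-params$gamma * t) *
    (w * cos(w * t) - params$gamma * sin(w * t))
}

# spatial factor 1 - (r0 - rp)^2 / epsilon^2 outside the patch, 0 inside
.spatial_factor <- function(rp, params) {
  ifelse(rp > params$patch_radius,
         1 - (params$r0 - rp)^2 / params$epsilon^2,
         0)
}

#' VEGFA concentration and its temporal derivative
#'
#' `vegf_concentration()` evaluates the prescribed field
#' \eqn{c(x,t)}; `vegf_concentration_rate()` its analytic time derivative
#' \eqn{\partial c/\partial t}. Both are identically zero on the patch
#' (\eqn{r_p \le} `patch_radius`).
#'
#' Either `point` or `t` may be vectorized (an n x 2 matrix of positions with
#' scalar `t`, or one position with a vector of times).
#'
#' @inheritParams distance_to_patch
#' @param t time in days, >= 0.
#' @return Numeric vector of concentrations (or rates, per day).
#' @examples
#' p <- vegf_params()
#' vegf_concentration(c(1, 0.5), 0, p)        # 0.39 * (1 - 4/8.41)
#' vegf_concentration_rate(c(1, 0.5), 0, p)   # 2*pi*0.115 * (1 - 4/8.41)
#' @export
vegf_concentration <- function(point, t, params = vegf_params()) {
  rp <- distance_to_patch(point, params)
  vegf_time_factor(t, params) * .spatial_factor(rp, params)
}

#' @rdname vegf_concentration
#' @export
vegf_concentration_rate <- function(point, t, params = vegf_params()) {
  rp <- distance_to_patch(point, params)
  vegf_time_factor_rate(t, params) * .spatial_factor(rp, params)
}

#' Boundaries between growth and rest periods
#'
#' Times in `(0, horizon]` at which the temporal derivative of the VEGFA
#' concentration changes sign. Intervals where \eqn{\partial c/\partial t > 0}
#' are growth periods (chemotactic drift active); where
#' \eqn{\partial c/\partial t \le 0}, rest periods (pure random motility).
#' The boundaries are position-independent because the spatial factor has a
#' fixed sign.
#'
#' The roots solve \eqn{\tan(2\pi\sigma t) = 2\pi\sigma/\gamma}, i.e.
#' \eqn{t_k = \{\arctan(2\pi\sigma/\gamma) + k\pi\}/(2\pi\sigma)}; for
#' \eqn{\gamma = 0} this reduces to the cosine zeros \eqn{(2k+1)/(4\sigma)}.
#'
#' @param params a [vegf_params()] object; `sigma` must be positive (a
#'   constant-in-time field has no period structure and is rejected).
#' @param horizon positive time horizon in days.
#' @return Ascending numeric vector of sign-change times (possibly empty).
#' @examples
#' period_boundaries(vegf_params(), 14)  # ~ 1.891, 6.238, 10.586
#' @export
period_boundaries <- function(params = vegf_params(), horizon = 14) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  if (params$sigma <= 0) {
    stop("period_boundaries(): sigma must be > 0 (constant-in-time field is degenerate)")
  }
  w <- 2 * pi * params$sigma
  # atan(w / gamma) in (0, pi/2]; gamma = 0 gives pi/2 (undamped cosine zeros)
  alpha <- if (params$gamma == 0) pi / 2 else atan(w / params$gamma)
  kmax <- ceiling((horizon * w - alpha) / pi) + 1
  roots <- (alpha + pi * seq(0, max(kmax, 0))) / w
  roots[roots > 0 & roots <= horizon]
}
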