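#' Simulation configuration
#'
#' All tunable parameters of a hybrid angiogenesis run. The defaults are the
#' published study conditions: unit square, `N = 100` cells per side, 20
#' sprout tips seeded on the right boundary (the pre-existing vessel), 14
#' simulated days, random motility `d = 0.0001728`, chemotactic strength
#' `beta = 1`, and the dimensionless VEGFA field of [vegf_params()].
#'
#' `t_branching` is the minimum sprout age (days) before a tip may branch; it
#' must be shorter than the first growth period (about 1.89 days with the
#' default field) for any early branching to occur -- the default is 0.5 days.
#' `length_scale_mm` converts dimensionless lengths to millimetres; the
#' default 3 mm is the mean in vivo distance between the arterial patch and
#' the pre-existing vessel (0.3 +/- 0.2 cm).
#'
#' @param d random motility coefficient (dimensionless), > 0 allowed 0 only
#'   with nonzero drift.
#' @param beta chemotactic strength \eqn{\beta}.
#' @param params a [vegf_params()] describing the VEGFA field.
#' @param N lattice cells per side.
#' @param n_tips initial sprout-tip count (at most `N`).
#' @param t_end simulation horizon (days).
#' @param t_branching minimum sprout age before branching eligibility (days).
#' @param safety safety factor in (0, 1] on the stable time step.
#' @param length_scale_mm physical length of the unit domain (mm).
#' @param snapshot_times times (days) at which tip states are recorded.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(d = 0.0001728, beta = 1, params = vegf_params(),
                       N = 100, n_tips = 20, t_end = 14, t_branching = 0.5,
                       safety = 0.9, length_scale_mm = 3,
                       snapshot_times = NULL) {
  if (is.null(snapshot_times)) snapshot_times <- 0:floor(t_end)
  stopifnot(d >= 0, beta >= 0, inherits(params, "vegf_params"),
            N >= 2, N == as.integer(N),
            n_tips >= 1, n_tips == as.integer(n_tips),
            t_end > 0, t_branching >= 0,
            safety > 0, safety <= 1, length_scale_mm > 0,
            all(snapshot_times >= 0), all(snapshot_times <= t_end))
  if (n_tips > N) {
    stop("n_tips > N: cannot place tips on the boundary column without collision")
  }
  structure(list(d = d, beta = beta, params = params, N = as.integer(N),
                 n_tips = as.integer(n_tips), t_end = t_end,
                 t_branching = t_branching, safety = safety,
                 length_scale_mm = length_scale_mm,
                 snapshot_times = sort(unique(as.numeric(snapshot_times)))),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Hybrid angiogenesis simulation configuration\n")
  cat(sprintf("  lattice N = %d (h = %g), %d tips, T = %g days\n",
              x$N, 1 / x$N, x$n_tips, x$t_end))
  cat(sprintf("  d = %g, beta = %g, T_branching = %g d, safety = %g, scale = %g mm\n",
              x$d, x$beta, x$t_branching, x$safety, x$length_scale_mm))
  print(x$params)
  invisible(x)
}
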