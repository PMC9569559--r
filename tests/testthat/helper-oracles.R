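# Independent oracles used across the suite.

# central finite difference of the concentration in time
fd_concentration_rate <- function(point, t, params, eps = 1e-6) {
  (vegf_concentration(point, t + eps, params) -
   vegf_concentration(point, max(t - eps, 0), params)) /
    (t + eps - max(t - eps, 0))
}

# sign-change times of the kinetic rate by grid scan + bisection
bisect_period_boundaries <- function(params, horizon, grid_n = 4000) {
  ts <- seq(1e-9, horizon, length.out = grid_n)
  g <- vegf_time_factor_rate(ts, params)
  flips <- which(g[-1] * g[-length(g)] < 0)
  vapply(flips, function(k) {
    uniroot(function(t) vegf_time_factor_rate(t, params),
            c(ts[k], ts[k + 1]), tol = 1e-12)$root
  }, 0)
}

# random admissible split velocity field on an N x N main lattice
random_split <- function(N, vmax = 1) {
  velocity_split(list(vx = matrix(runif(N * N, -vmax, vmax), N, N),
                      vy = matrix(runif(N * N, -vmax, vmax), N, N)))
}

random_density <- function(N) {
  matrix(runif(N * N), N, N)
}

lattice_mass <- function(n, h) sum(n) * h^2
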