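test_that("advective flux is upwind and vanishes with the velocity", {
  N <- 4
  n <- random_density(N)
  z <- velocity_split(list(vx = matrix(0, N, N), vy = matrix(0, N, N)))
  G <- advective_flux(n, z)
  expect_equal(G$Gx, matrix(0, N + 1, N))
  expect_equal(G$Gy, matrix(0, N, N + 1))
  # uniform density, uniform positive x-velocity: interior x-faces carry v
  v <- 0.7
  s <- velocity_split(list(vx = matrix(v, N, N), vy = matrix(0, N, N)))
  G <- advective_flux(matrix(1, N, N), s)
  expect_equal(G$Gx[2:N, ], matrix(v, N - 1, N))
  expect_equal(G$Gx[c(1, N + 1), ], matrix(0, 2, N))  # walls carry nothing
  # point mass with leftward velocity: only its left face carries (negative) flux
  n <- matrix(0, N, N); n[3, 2] <- 1
  s <- velocity_split(list(vx = matrix(-0.3, N, N), vy = matrix(0, N, N)))
  G <- advective_flux(n, s)
  expected <- matrix(0, N + 1, N); expected[3, 2] <- -0.3
  expect_equal(G$Gx, expected)
  expect_equal(G$Gy, matrix(0, N, N + 1))
})

test_that("total flux adds diffusion and closes the boundary exactly", {
  N <- 4; h <- 1 / N; d <- 0.01
  z <- velocity_split(list(vx = matrix(0, N, N), vy = matrix(0, N, N)))
  n <- matrix(2.5, N, N)
  Fl <- total_flux(n, advective_flux(n, z), d, h)
  expect_equal(Fl$Fx, matrix(0, N + 1, N))
  expect_equal(Fl$Fy, matrix(0, N, N + 1))
  # boundary faces are zero no matter the data
  set.seed(2)
  n <- random_density(N)
  s <- random_split(N)
  Fl <- total_flux(n, advective_flux(n, s), d, h)
  expect_equal(Fl$Fx[c(1, N + 1), ], matrix(0, 2, N))
  expect_equal(Fl$Fy[, c(1, N + 1)], matrix(0, N, 2))
  # step profile across one face, no advection: -d * dn / h on that face only
  n <- matrix(0, N, N); n[1:2, ] <- 1
  Fl <- total_flux(n, advective_flux(n, z), d, h)
  expected <- matrix(0, N + 1, N); expected[3, ] <- d / h
  expect_equal(Fl$Fx, expected)
  expect_equal(Fl$Fy, matrix(0, N, N + 1))
})

test_that("stable timestep follows the stability bound", {
  expect_equal(stable_timestep(0.0001728, 0.01, 0, safety = 1),
               0.01^2 / (4 * 0.0001728), tolerance = 1e-12)
  expect_equal(stable_timestep(0.0001728, 0.01, 0, safety = 1), 0.14468,
               tolerance = 1e-4)
  t1 <- stable_timestep(0.001, 0.02, 1)
  expect_lt(stable_timestep(0.001, 0.02, 2), t1)
  expect_equal(stable_timestep(0.001, 0.01, 0), stable_timestep(0.001, 0.02, 0) / 4)
  expect_error(stable_timestep(0, 0.01, 0), "no dynamics")
})

test_that("transition probabilities form a probability distribution per site", {
  N <- 8; h <- 1 / N; d <- 0.02
  z <- velocity_split(list(vx = matrix(0, N, N), vy = matrix(0, N, N)))
  # zero velocity at the stability edge: pure quarter moves in the interior
  tau <- h^2 / (4 * d)
  P <- transition_probabilities(z, d, h, tau)
  expect_equal(tip_transition(P, 4, 5),
               c(stay = 0, left = 0.25, right = 0.25, down = 0.25, up = 0.25),
               tolerance = 1e-12)
  # wall-facing moves fold into stay at edges and corners
  expect_equal(unname(tip_transition(P, 1, 1)), c(0.5, 0, 0.25, 0, 0.25),
               tolerance = 1e-12)
  # any admissible tau: stay 1 - 4 d tau / h^2, quarter split of the rest
  tau <- 0.4 * h^2 / (4 * d)
  P <- transition_probabilities(z, d, h, tau)
  expect_equal(unname(tip_transition(P, 3, 3)[1]), 0.6, tolerance = 1e-12)
  expect_equal(unname(tip_transition(P, 3, 3)[2]), 0.1, tolerance = 1e-12)
  # random admissible velocity fields: normalization and nonnegativity
  set.seed(14)
  for (rep in 1:20) {
    s <- random_split(N, vmax = 2)
    tau <- stable_timestep(d, h, s, safety = runif(1, 0.3, 1))
    P <- transition_probabilities(s, d, h, tau)
    tot <- P$stay + P$left + P$right + P$down + P$up
    expect_lt(max(abs(tot - 1)), 1e-12)
    expect_gte(min(P$stay, P$left, P$right, P$down, P$up), 0)
  }
  # violating the bound is an explicit failure
  s <- random_split(N, vmax = 2)
  bad <- 1.2 * stable_timestep(d, h, s, safety = 1)
  expect_error(transition_probabilities(s, d, h, bad), "stability bound")
})

test_that("density step preserves mass, positivity and uniform fixed points", {
  N <- 16; h <- 1 / N; d <- 0.05
  z <- velocity_split(list(vx = matrix(0, N, N), vy = matrix(0, N, N)))
  tau <- stable_timestep(d, h, z)
  n <- matrix(3, N, N)
  P <- transition_probabilities(z, d, h, tau)
  expect_equal(density_step(n, P), n, tolerance = 1e-14)
  # point mass at the stability edge splits into quarters
  tau_edge <- h^2 / (4 * d)
  P <- transition_probabilities(z, d, h, tau_edge)
  n <- matrix(0, N, N); n[8, 8] <- 1
  n1 <- density_step(n, P)
  expect_equal(n1[8, 8], 0)
  expect_equal(c(n1[7, 8], n1[9, 8], n1[8, 7], n1[8, 9]), rep(0.25, 4))
  expect_equal(sum(n1), 1)
  # 1000 steps under fresh random admissible velocities
  set.seed(5)
  n <- random_density(N)
  m0 <- lattice_mass(n, h)
  for (k in 1:1000) {
    s <- random_split(N, vmax = 1.5)
    tau <- stable_timestep(d, h, s)
    n <- density_step(n, transition_probabilities(s, d, h, tau))
  }
  expect_lt(abs(lattice_mass(n, h) - m0), 1e-10)
  expect_gte(min(n), 0)
})

test_that("flux form and probability form are the same operator", {
  set.seed(33)
  N <- 8; h <- 1 / N; d <- 0.03
  for (rep in 1:20) {
    n <- random_density(N)
    s <- random_split(N, vmax = 2)
    tau <- stable_timestep(d, h, s, safety = runif(1, 0.2, 1))
    via_prob <- density_step(n, transition_probabilities(s, d, h, tau))
    via_flux <- density_step_flux(n, s, d, h, tau)
    expect_lt(max(abs(via_prob - via_flux)), 1e-12)
  }
})

test_that("pure diffusion relaxes to the uniform distribution", {
  N <- 16; h <- 1 / N; d <- 0.05
  z <- velocity_split(list(vx = matrix(0, N, N), vy = matrix(0, N, N)))
  tau <- stable_timestep(d, h, z)
  P <- transition_probabilities(z, d, h, tau)
  n <- matrix(0, N, N); n[2, 13] <- 1
  target <- mean(n)
  dist <- max(abs(n - target))
  checkpoints <- numeric(0)
  for (k in 1:2500) {
    n <- density_step(n, P)
    if (k %% 500 == 0) checkpoints <- c(checkpoints, max(abs(n - target)))
  }
  expect_true(all(diff(checkpoints) < 0))
  expect_lt(max(abs(n - target)), 1e-6)
})
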