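# Sprout-tip agents and the hybrid simulation loop.
#
# Tips are biased random walkers on the main lattice whose movement
# probabilities are the stencil weights of the continuum scheme, so the
# expected tip flux matches the density equation.

# -- tip agent -----------------------------------------------------------

.new_tip <- function(id, i, j, birth_time, parent_id = NA_integer_,
                     root_id = id) {
  structure(list(id = id, i = i, j = j, birth_time = birth_time,
                 state = "active", parent_id = parent_id, root_id = root_id,
                 arrival_time = NA_real_,
                 trajectory = data.frame(t = birth_time, i = i, j = j)),
            class = "tip_agent")
}

#' @export
print.tip_agent <- function(x, ...) {
  cat(sprintf("Tip %d at (%d, %d), state %s, born t = %g (%d recorded sites)\n",
              x$id, x$i, x$j, x$state, x$birth_time, nrow(x$trajectory)))
  invisible(x)
}

# -- movement kernels (shared by the op functions and the fast loop) ------

# direction from a 5-tuple (stay, left, right, down, up) and a uniform draw
.sample_move <- function(p, u) {
  c1 <- p[2]; c2 <- c1 + p[3]; c3 <- c2 + p[4]; c4 <- c3 + p[5]
  if (u < c1) 1L else if (u < c2) 2L else if (u < c3) 3L else if (u < c4) 4L else 0L
}

.DIR_I <- c(0L, -1L, 1L, 0L, 0L)  # stay, left, right, down, up
.DIR_J <- c(0L, 0L, 0L, -1L, 1L)

# folded 5-tuple at one site from split velocity components (NULL = rest)
.tip_probs <- function(i, j, vx, vy, d, h, tau, N) {
  if (is.null(vx)) {
    v1p <- 0; v1m <- 0; v2p <- 0; v2m <- 0
  } else {
    v1 <- vx[i, j]; v2 <- vy[i, j]
    v1p <- max(0, v1); v1m <- max(0, -v1)
    v2p <- max(0, v2); v2m <- max(0, -v2)
  }
  pdif <- d * tau / h^2
  adv <- tau / h
  left  <- pdif + adv * v1m
  right <- pdif + adv * v1p
  down  <- pdif + adv * v2m
  up    <- pdif + adv * v2p
  stay <- 1 - left - right - down - up
  if (i == 1L) { stay <- stay + left;  left  <- 0 }
  if (i == N)  { stay <- stay + right; right <- 0 }
  if (j == 1L) { stay <- stay + down;  down  <- 0 }
  if (j == N)  { stay <- stay + up;    up    <- 0 }
  c(stay, left, right, down, up)
}

#' Transition 5-tuple at a single lattice site
#'
#' Convenience accessor returning the (stay, left, right, down, up) tuple of
#' a [transition_probabilities()] object at main-lattice site `(i, j)` -- the
#' probabilities a tip at that site moves with.
#'
#' @param probs a [transition_probabilities()].
#' @param i,j 1-based main-lattice indices.
#' @return Named numeric vector of length 5 summing to 1.
#' @export
tip_transition <- function(probs, i, j) {
  stopifnot(inherits(probs, "transition_probabilities"))
  c(stay = probs$stay[i, j], left = probs$left[i, j],
    right = probs$right[i, j], down = probs$down[i, j], up = probs$up[i, j])
}

# -- agent operations ----------------------------------------------------

#' Place the initial sprout tips on the right boundary
#'
#' Seeds `n_tips` agents in the boundary column `i = N` (the pre-existing
#' vessel at x = 1), with row indices drawn uniformly *without replacement*
#' so no two tips share a starting site. Uses the current RNG state; seed it
#' with [set.seed()] for reproducibility.
#'
#' @param config a [sim_config()].
#' @param network optionally, a [vessel_network()] to seed with the starting
#'   sites.
#' @return List of `tip_agent` objects with ids `1..n_tips`, birth time 0.
#' @export
initialize_tips <- function(config, network = NULL) {
  N <- config$N
  rows <- sample.int(N, config$n_tips)
  tips <- lapply(seq_len(config$n_tips), function(k) {
    .new_tip(id = k, i = N, j = rows[k], birth_time = 0)
  })
  if (!is.null(network)) {
    for (tp in tips) network_claim(network, tp$i, tp$j, tp$id)
  }
  tips
}

#' Move a tip by one probabilistic step
#'
#' Samples one of stay/left/right/down/up from the 5-tuple `p` (one uniform
#' draw from the current RNG) and commits the move: the tip's site is updated
#' and, if the site changed, appended to its trajectory with time stamp `t`.
#' Stay steps append nothing.
#'
#' @param tip a `tip_agent`.
#' @param p numeric length-5 probability tuple (stay, left, right, down, up).
#' @param t time stamp (days) for the new trajectory entry.
#' @return The updated tip.
#' @export
move_tip <- function(tip, p, t = NA_real_) {
  stopifnot(inherits(tip, "tip_agent"), tip$state == "active",
            length(p) == 5L, all(p >= -1e-12))
  if (abs(sum(p) - 1) > 1e-9) stop("move probabilities must sum to 1")
  dir <- .sample_move(p, runif(1))
  if (dir > 0L) {
    tip$i <- tip$i + .DIR_I[dir + 1L]
    tip$j <- tip$j + .DIR_J[dir + 1L]
    tip$trajectory <- rbind(tip$trajectory,
                            data.frame(t = t, i = tip$i, j = tip$j))
  }
  tip
}

#' Occupancy network of vessel trajectories
#'
#' Mutable map from main-lattice sites to the id of the first tip whose
#' trajectory claimed the site. Occupancy is never removed; the earliest
#' occupant always owns the site.
#'
#' @param N lattice cells per side.
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(N) {
  structure(list(env = list2env(list(occ = integer(N * N)), parent = emptyenv()),
                 N = as.integer(N)),
            class = "vessel_network")
}

#' @rdname vessel_network
#' @param network a `vessel_network`.
#' @param i,j main-lattice site.
#' @param id claiming tip id.
#' @return `network_claim()` returns the owning id after the claim (the
#'   existing owner if the site was taken); `network_owner()` the owner id or
#'   `NA` if unclaimed.
#' @export
network_claim <- function(network, i, j, id) {
  key <- (i - 1L) * network$N + j
  cur <- network$env$occ[key]
  if (cur == 0L) {
    network$env$occ[key] <- as.integer(id)
    as.integer(id)
  } else {
    cur
  }
}

#' @rdname vessel_network
#' @export
network_owner <- function(network, i, j) {
  cur <- network$env$occ[(i - 1L) * network$N + j]
  if (cur == 0L) NA_integer_ else cur
}

#' Anastomosis check after a move
#'
#' If the site a tip just moved to is already part of a *different* tip's
#' trail, the moving tip fuses there and terminates (state `anastomosed`);
#' the prior occupant is unaffected and keeps the site. A tip staying in
#' place, or stepping on a site it claimed itself, is exempt. An unclaimed
#' site is claimed for the moving tip. When two tips propose the same empty
#' site in one step, processing order (ascending id) admits the first and
#' the second anastomoses.
#'
#' @param tip a `tip_agent` that has just moved (or stayed).
#' @param proposed integer length-2, the site the tip moved to.
#' @param network the [vessel_network()].
#' @param previous the tip's site before the move (stay steps are exempt).
#' @return The tip, possibly with state `anastomosed`.
#' @export
apply_anastomosis <- function(tip, proposed, network,
                              previous = proposed) {
  stopifnot(inherits(tip, "tip_agent"), inherits(network, "vessel_network"))
  if (proposed[1] == previous[1] && proposed[2] == previous[2]) return(tip)
  owner <- network_claim(network, proposed[1], proposed[2], tip$id)
  if (owner != tip$id) tip$state <- "anastomosed"
  tip
}

#' Patch-arrival check
#'
#' A tip whose site center lies within `patch_radius + h` of the patch
#' center has reached the patch periphery: its state becomes `arrived`, the
#' arrival time is recorded, and it stops moving. The one-cell tolerance `h`
#' accounts for the patch interior carrying no lattice site centers at
#' coarse resolution.
#'
#' @param tip a `tip_agent`.
#' @param params a [vegf_params()].
#' @param h grid spacing.
#' @param t current time (days), recorded as the arrival time.
#' @return The tip, possibly with state `arrived`.
#' @export
check_patch_arrival <- function(tip, params, h, t) {
  stopifnot(inherits(tip, "tip_agent"))
  if (tip$state != "active") return(tip)
  site <- c((tip$i - 0.5) * h, (tip$j - 0.5) * h)
  if (distance_to_patch(site, params) <= params$patch_radius + h) {
    tip$state <- "arrived"
    tip$arrival_time <- t
  }
  tip
}

#' Branching probability of a sprout tip
#'
#' Piecewise-constant in the local dimensionless VEGFA concentration:
#' 0 for c < 0.25, 0.3 on \[0.25, 0.45), 0.4 on \[0.45, 0.60), 0.5 on
#' \[0.60, 0.70), and 1 at or above 0.70. Branching requires the sprout's
#' age to exceed the threshold `t_branching` and applies only while the
#' temporal change of the VEGFA concentration is positive; either gate
#' failing returns 0 regardless of the table.
#'
#' @param c local VEGFA concentration (dimensionless, >= 0; vectorized).
#' @param ct_sign sign of the local temporal VEGFA derivative.
#' @param age sprout age in days.
#' @param t_branching minimum age for branching eligibility (days).
#' @return Branching probability per movement step.
#' @examples
#' branching_probability(0.5, ct_sign = 1, age = 1, t_branching = 0.5)  # 0.4
#' @export
branching_probability <- function(c, ct_sign = 1, age = Inf,
                                  t_branching = 0.5) {
  stopifnot(all(c >= 0))
  if (ct_sign <= 0 || age < t_branching) return(rep(0, length(c)))
  ifelse(c < 0.25, 0,
  ifelse(c < 0.45, 0.3,
  ifelse(c < 0.60, 0.4,
  ifelse(c < 0.70, 0.5, 1))))
}

#' Spawn a daughter tip by branching
#'
#' With the given probability (one uniform draw), spawns a new sprout tip at
#' the parent's current site. The daughter inherits nothing but position:
#' her age restarts at zero, and her trajectory accrues to the parent's
#' root lineage (`root_id`) for vessel-level measurement. At most one
#' daughter per tip per step.
#'
#' @param tip the parent `tip_agent` (active).
#' @param probability branching probability from [branching_probability()].
#' @param t current time (days), the daughter's birth time.
#' @param next_id id to assign the daughter.
#' @return A new `tip_agent`, or `NULL` if no branching occurred.
#' @export
apply_branching <- function(tip, probability, t, next_id) {
  stopifnot(inherits(tip, "tip_agent"), tip$state == "active",
            probability >= 0, probability <= 1)
  if (probability <= 0) return(NULL)
  if (runif(1) >= probability) return(NULL)
  .new_tip(id = next_id, i = tip$i, j = tip$j, birth_time = t,
           parent_id = tip$id, root_id = tip$root_id)
}

# -- the simulation loop -------------------------------------------------

# growing row log (list-backed, amortized append)
.new_log <- function(cols, cap = 1024L) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$rows <- vector("list", cap)
  e$cols <- cols
  e
}

.log_add <- function(e, row) {
  n <- e$n + 1L
  if (n > length(e$rows)) length(e$rows) <- 2L * length(e$rows)
  e$rows[[n]] <- row
  e$n <- n
  invisible(e)
}

.log_df <- function(e) {
  if (e$n == 0L) {
    out <- rep(list(numeric(0)), length(e$cols))
    names(out) <- e$cols
    return(as.data.frame(out))
  }
  m <- matrix(unlist(e$rows[seq_len(e$n)], use.names = FALSE),
              ncol = length(e$cols), byrow = TRUE)
  colnames(m) <- e$cols
  as.data.frame(m)
}

#' Run the hybrid angiogenesis simulation
#'
#' The full loop: at each adaptive step the chemotactic potential is
#' evaluated analytically on the sub-lattice, the transport velocity and its
#' upwind split are formed on the main lattice, the stable time increment is
#' chosen, every active tip takes one probabilistic step (ascending id, with
#' anastomosis resolved against the continuously updated occupancy), arrivals
#' are checked, and then age- and signal-gated branching may spawn daughters.
#' Snapshots of all tips are recorded at the configured times. The run is
#' fully deterministic given `(config, seed)`.
#'
#' The potential factorizes into a time factor and a fixed spatial profile,
#' and the gradient stencil is linear, so the velocity field is the cached
#' spatial gradient scaled by the time-factor rate each step.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed, recorded in the result.
#' @return An object of class `angio_sim`: list with elements `tips` (one
#'   row per tip: id, root/parent links, birth and final site, state,
#'   arrival time, dimensionless extent/root-extent/path), `moves` (every
#'   site change: tip_id, step, t, i, j), `events` (branching, anastomosis
#'   and arrival events), `snapshots` (per configured time, the per-tip state
#'   and running measurements), `arrival_times`, `config`, `seed`, `n_steps`,
#'   `t_final`.
#' @examples
#' \donttest{
#' res <- run_simulation(sim_config(), seed = 1)
#' res
#' }
#' @export
run_simulation <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  N <- config$N
  h <- 1 / N
  d <- config$d
  prm <- config$params
  lat <- dual_lattice(N)

  # cached spatial profiles: the field factorizes as time x space
  xs <- lat$x_sub
  rp_sub <- sqrt(outer((xs - prm$patch_center[1])^2,
                       (xs - prm$patch_center[2])^2, "+"))
  S_sub <- .spatial_factor(rp_sub, prm)
  xm <- lat$x_main
  rp_main <- sqrt(outer((xm - prm$patch_center[1])^2,
                        (xm - prm$patch_center[2])^2, "+"))
  S_main <- .spatial_factor(rp_main, prm)
  # unit-rate velocity: gradient of (-beta * S); scaled by ct time factor
  v0 <- velocity_on_main_lattice(-config$beta * S_sub, h)
  vhat0 <- max(abs(v0$vx), abs(v0$vy))
  if (d == 0 && (vhat0 == 0 || config$beta == 0)) {
    stop("no dynamics: d = 0 and the chemotactic velocity vanishes")
  }

  # tip registry (vectors for speed; ops match the exported agent functions)
  cap <- max(64L, 4L * config$n_tips)
  tip_i <- integer(cap); tip_j <- integer(cap)
  birth <- numeric(cap); root <- integer(cap); parent <- rep(NA_integer_, cap)
  state <- integer(cap)               # 0 active, 1 anastomosed, 2 arrived
  arr_t <- rep(NA_real_, cap)
  oi <- integer(cap); oj <- integer(cap)   # own origin
  ext <- numeric(cap); rext <- numeric(cap); path <- numeric(cap)
  n_tip <- config$n_tips
  grow <- function(need) {
    while (need > cap) {
      cap <<- cap * 2L
      length(tip_i) <<- cap; length(tip_j) <<- cap
      length(birth) <<- cap; length(root) <<- cap
      parent <<- c(parent, rep(NA_integer_, cap - length(parent)))
      length(state) <<- cap
      arr_t <<- c(arr_t, rep(NA_real_, cap - length(arr_t)))
      length(oi) <<- cap; length(oj) <<- cap
      length(ext) <<- cap; length(rext) <<- cap; length(path) <<- cap
    }
  }

  occ <- integer(N * N)
  rows <- sample.int(N, config$n_tips)
  moves <- .new_log(c("tip_id", "step", "t", "i", "j"))
  events <- .new_log(c("t", "type", "tip_id", "other_id"))  # type 1 branch, 2 anastomosis, 3 arrival
  for (k in seq_len(config$n_tips)) {
    tip_i[k] <- N; tip_j[k] <- rows[k]
    birth[k] <- 0; root[k] <- k; state[k] <- 0L
    oi[k] <- N; oj[k] <- rows[k]
    occ[(N - 1L) * N + rows[k]] <- k
    .log_add(moves, c(k, 0, 0, N, rows[k]))
  }

  snaps <- list()
  take_snapshot <- function(tm) {
    idx <- seq_len(n_tip)
    snaps[[sprintf("%g", tm)]] <<- data.frame(
      id = idx, root_id = root[idx], parent_id = parent[idx],
      i = tip_i[idx], j = tip_j[idx],
      state = c("active", "anastomosed", "arrived")[state[idx] + 1L],
      birth_time = birth[idx], extent = ext[idx], root_extent = rext[idx],
      path = path[idx])
  }
  pending <- config$snapshot_times
  if (length(pending) && pending[1] == 0) {
    take_snapshot(0)
    pending <- pending[-1]
  }

  arrive_r <- prm$patch_radius + h
  t <- 0
  step <- 0L
  while (t < config$t_end - 1e-9 && any(state[seq_len(n_tip)] == 0L)) {
    g <- vegf_time_factor_rate(t, prm)   # ct = g * S; sign uniform in space
    if (g > 0) {
      vx <- g * v0$vx; vy <- g * v0$vy; vhat <- g * vhat0
    } else {
      vx <- NULL; vy <- NULL; vhat <- 0
    }
    tau <- stable_timestep(d, h, vhat, config$safety)
    tau <- min(tau, config$t_end - t,
               if (length(pending)) pending[1] - t else Inf)
    t_new <- t + tau
    step <- step + 1L

    active <- which(state[seq_len(n_tip)] == 0L)
    # movement + anastomosis, ascending id against updated occupancy
    for (k in active) {
      p <- .tip_probs(tip_i[k], tip_j[k], vx, vy, d, h, tau, N)
      dir <- .sample_move(p, runif(1))
      if (dir == 0L) next
      ni <- tip_i[k] + .DIR_I[dir + 1L]
      nj <- tip_j[k] + .DIR_J[dir + 1L]
      key <- (ni - 1L) * N + nj
      owner <- occ[key]
      if (owner == 0L) occ[key] <- k
      tip_i[k] <- ni; tip_j[k] <- nj
      .log_add(moves, c(k, step, t_new, ni, nj))
      ext[k] <- max(ext[k], h * sqrt((ni - oi[k])^2 + (nj - oj[k])^2))
      rr <- root[k]
      rext[k] <- max(rext[k], h * sqrt((ni - oi[rr])^2 + (nj - oj[rr])^2))
      path[k] <- path[k] + h
      if (owner != 0L && owner != k) {
        state[k] <- 1L
        .log_add(events, c(t_new, 2, k, owner))
      }
    }
    # arrival checks
    for (k in which(state[seq_len(n_tip)] == 0L)) {
      rp <- sqrt(((tip_i[k] - 0.5) * h - prm$patch_center[1])^2 +
                 ((tip_j[k] - 0.5) * h - prm$patch_center[2])^2)
      if (rp <= arrive_r) {
        state[k] <- 2L
        arr_t[k] <- t_new
        .log_add(events, c(t_new, 3, k, NA))
      }
    }
    # branching (only while VEGFA is rising at the tip's site)
    if (g > 0) {
      for (k in which(state[seq_len(n_tip)] == 0L)) {
        if (t - birth[k] < config$t_branching) next
        if (S_main[tip_i[k], tip_j[k]] <= 0) next   # ct = 0 at the site
        cc <- vegf_time_factor(t, prm) * S_main[tip_i[k], tip_j[k]]
        pb <- branching_probability(cc, ct_sign = 1, age = Inf)
        if (pb <= 0) next
        if (runif(1) < pb) {
          n_tip <- n_tip + 1L
          grow(n_tip)
          m <- n_tip
          tip_i[m] <- tip_i[k]; tip_j[m] <- tip_j[k]
          birth[m] <- t; root[m] <- root[k]; parent[m] <- k
          state[m] <- 0L
          oi[m] <- tip_i[k]; oj[m] <- tip_j[k]
          rext[m] <- h * sqrt((tip_i[m] - oi[root[m]])^2 +
                              (tip_j[m] - oj[root[m]])^2)
          .log_add(moves, c(m, step, t, tip_i[m], tip_j[m]))
          .log_add(events, c(t, 1, m, k))
        }
      }
    }

    t <- t_new
    while (length(pending) && t >= pending[1] - 1e-9) {
      take_snapshot(pending[1])
      pending <- pending[-1]
    }
  }
  # freeze remaining snapshots if the run emptied early
  while (length(pending)) {
    take_snapshot(pending[1])
    pending <- pending[-1]
  }

  idx <- seq_len(n_tip)
  tips <- data.frame(
    id = idx, root_id = root[idx], parent_id = parent[idx],
    birth_time = birth[idx], i0 = oi[idx], j0 = oj[idx],
    i = tip_i[idx], j = tip_j[idx],
    state = c("active", "anastomosed", "arrived")[state[idx] + 1L],
    arrival_time = arr_t[idx], extent = ext[idx], root_extent = rext[idx],
    path = path[idx])
  ev <- .log_df(events)
  ev$type <- c("branching", "anastomosis", "arrival")[ev$type]
  structure(list(tips = tips, moves = .log_df(moves), events = ev,
                 snapshots = snaps,
                 arrival_times = sort(arr_t[idx][!is.na(arr_t[idx])]),
                 config = config, seed = seed, n_steps = step, t_final = t),
            class = "angio_sim")
}

#' @export
print.angio_sim <- function(x, ...) {
  st <- table(factor(x$tips$state,
                     levels = c("active", "anastomosed", "arrived")))
  cat(sprintf("Hybrid angiogenesis run (seed %d): %d steps to t = %g days\n",
              x$seed, x$n_steps, x$t_final))
  cat(sprintf("  %d tips spawned (%d initial): %d active, %d anastomosed, %d arrived\n",
              nrow(x$tips), x$config$n_tips,
              st[["active"]], st[["anastomosed"]], st[["arrived"]]))
  if (length(x$arrival_times)) {
    cat(sprintf("  first patch arrival at t = %.2f days\n", x$arrival_times[1]))
  } else {
    cat("  no tip reached the patch\n")
  }
  invisible(x)
}
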