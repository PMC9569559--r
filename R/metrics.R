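# Vessel-length measurement mirroring the in vivo protocol: a vessel is an
# initial sprout lineage (root tip plus all descendants), and its extent is
# the straight-line distance from the root origin on the pre-existing vessel
# to the farthest point any member ever visited -- the in vivo measurement
# from the arteriole circumference to the farthest point of the new vessel.

#' Extent and path length of a trajectory
#'
#' `extent` is the maximum Euclidean distance from the origin over all
#' visited sites, scaled to mm; `path` is the total arc length (stay steps
#' contribute nothing). Extent never exceeds path.
#'
#' @param trajectory data frame (or matrix) with columns `i`, `j`: visited
#'   main-lattice sites in order.
#' @param h grid spacing.
#' @param origin integer length-2 origin site; defaults to the first
#'   trajectory row.
#' @param length_scale_mm physical length of the unit domain (mm).
#' @return List with `extent_mm` and `path_mm`.
#' @examples
#' walk <- data.frame(i = 100:90, j = rep(50, 11))
#' vessel_extent(walk, h = 0.01)   # 0.3 mm out of a 10-cell straight walk
#' @export
vessel_extent <- function(trajectory, h, origin = NULL,
                          length_scale_mm = 3) {
  tr <- as.data.frame(trajectory)
  stopifnot(nrow(tr) >= 1L, all(c("i", "j") %in% names(tr)),
            h > 0, length_scale_mm > 0)
  if (is.null(origin)) origin <- c(tr$i[1], tr$j[1])
  dd <- h * sqrt((tr$i - origin[1])^2 + (tr$j - origin[2])^2)
  steps <- if (nrow(tr) > 1L) {
    h * sqrt(diff(tr$i)^2 + diff(tr$j)^2)
  } else 0
  list(extent_mm = max(dd) * length_scale_mm,
       path_mm = sum(steps) * length_scale_mm)
}

# per-lineage extents (dimensionless) from a per-tip table carrying
# root_id and the running max distance from the root origin
.lineage_extents <- function(df) {
  tapply(df$root_extent, df$root_id, max)
}

#' Final vessel lengths of a run
#'
#' One length per initial sprout lineage: the straight-line extent from the
#' lineage's origin on the right boundary to the farthest point visited by
#' the root tip or any of its descendants, in mm.
#'
#' @param result an `angio_sim` from [run_simulation()].
#' @return Named numeric vector (one entry per initial tip).
#' @export
final_vessel_lengths <- function(result) {
  stopifnot(inherits(result, "angio_sim"))
  le <- .lineage_extents(result$tips) * result$config$length_scale_mm
  setNames(as.numeric(le), names(le))
}

#' Per-day vessel growth curve
#'
#' For each snapshot day, the mean and SD over vessels (initial sprout
#' lineages) of the vessel extent accrued by that day, in mm. The extent is
#' a running maximum, so the curve is nondecreasing.
#'
#' @param result an `angio_sim` with recorded snapshots.
#' @return Data frame of class `growth_curve` with columns `day`, `mean_mm`,
#'   `sd_mm`, `n`.
#' @export
growth_curve <- function(result) {
  stopifnot(inherits(result, "angio_sim"))
  if (length(result$snapshots) == 0L) {
    stop("growth_curve(): the run recorded no snapshots")
  }
  scale <- result$config$length_scale_mm
  days <- as.numeric(names(result$snapshots))
  rows <- lapply(seq_along(days), function(k) {
    le <- .lineage_extents(result$snapshots[[k]]) * scale
    data.frame(day = days[k], mean_mm = mean(le), sd_mm = sd(le),
               n = length(le))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Recompute the growth curve from a trajectories table
#'
#' Independent path for the same measurement: rebuilds each vessel's running
#' extent directly from the logged site visits, for round-trip checks against
#' the in-memory curve.
#'
#' @param moves data frame with columns `tip_id`, `t`, `i`, `j` (as written
#'   by [write_run()] or carried in an `angio_sim`).
#' @param tips per-tip table with `id`, `root_id`, `i0`, `j0`.
#' @param days days at which to evaluate the curve.
#' @param h grid spacing.
#' @param length_scale_mm physical length of the unit domain (mm).
#' @return A `growth_curve` data frame.
#' @export
growth_curve_from_moves <- function(moves, tips, days, h,
                                    length_scale_mm = 3) {
  stopifnot(all(c("tip_id", "t", "i", "j") %in% names(moves)),
            all(c("id", "root_id", "i0", "j0") %in% names(tips)))
  root <- tips$root_id[match(moves$tip_id, tips$id)]
  oi <- tips$i0[match(root, tips$id)]
  oj <- tips$j0[match(root, tips$id)]
  dd <- h * sqrt((moves$i - oi)^2 + (moves$j - oj)^2)
  roots <- sort(unique(tips$root_id))
  rows <- lapply(days, function(D) {
    sel <- moves$t <= D + 1e-9
    le <- rep(0, length(roots))
    names(le) <- roots
    if (any(sel)) {
      mx <- tapply(dd[sel], factor(root[sel], levels = roots), max)
      mx[is.na(mx)] <- 0
      le <- mx
    }
    le <- le * length_scale_mm
    data.frame(day = D, mean_mm = mean(le), sd_mm = sd(le), n = length(le))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Pooled mean and SD of replicate measurements
#'
#' Sample mean and sample SD (n - 1 denominator) of measurements pooled
#' across replicate runs.
#'
#' @param measurements numeric vector, or list of numeric vectors to pool.
#' @return Named numeric vector `mean`, `sd`, `n`.
#' @examples
#' summarize_replicates(c(1, 2, 3))   # mean 2, sd 1
#' @export
summarize_replicates <- function(measurements) {
  x <- if (is.list(measurements)) unlist(measurements, use.names = FALSE)
       else measurements
  stopifnot(is.numeric(x))
  if (length(x) < 2L) stop("need at least 2 measurements for an SD")
  c(mean = mean(x), sd = sd(x), n = length(x))
}

#' Run a seeded ensemble of simulations
#'
#' Runs [run_simulation()] once per seed and collects per-run arrival
#' statistics, final vessel lengths and growth curves.
#'
#' @param config a [sim_config()].
#' @param seeds integer vector of seeds.
#' @param keep_runs keep the full `angio_sim` objects (memory-heavy).
#' @return An object of class `angio_ensemble`: list with `per_run` (data
#'   frame: seed, n_arrived, first_arrival, n_tips_total), `lengths` (list of
#'   per-run final vessel lengths, mm), `curves` (list of growth curves),
#'   `config`, and optionally `runs`.
#' @export
run_ensemble <- function(config = sim_config(), seeds = 1:50,
                         keep_runs = FALSE) {
  runs <- lapply(seeds, function(s) run_simulation(config, seed = s))
  per_run <- data.frame(
    seed = seeds,
    n_arrived = vapply(runs, function(r) sum(r$tips$state == "arrived"), 0L),
    first_arrival = vapply(runs, function(r) {
      if (length(r$arrival_times)) r$arrival_times[1] else NA_real_
    }, 0),
    n_tips_total = vapply(runs, function(r) nrow(r$tips), 0L))
  out <- list(per_run = per_run,
              lengths = lapply(runs, final_vessel_lengths),
              curves = lapply(runs, growth_curve),
              config = config)
  if (keep_runs) out$runs <- runs
  structure(out, class = "angio_ensemble")
}

#' @export
print.angio_ensemble <- function(x, ...) {
  pr <- x$per_run
  pooled <- summarize_replicates(x$lengths)
  cat(sprintf("Angiogenesis ensemble: %d runs\n", nrow(pr)))
  cat(sprintf("  arrivals/run: %s (max %d); runs with arrival: %d/%d\n",
              paste(range(pr$n_arrived), collapse = "-"), max(pr$n_arrived),
              sum(!is.na(pr$first_arrival)), nrow(pr)))
  if (any(!is.na(pr$first_arrival))) {
    cat(sprintf("  median first arrival: %.2f days\n",
                median(pr$first_arrival, na.rm = TRUE)))
  }
  cat(sprintf("  pooled final vessel length: %.3f +/- %.3f mm (n = %d)\n",
              pooled["mean"], pooled["sd"], pooled["n"]))
  invisible(x)
}

#' Across-seed mean growth curve
#'
#' Averages the per-run lineage-mean extents day by day across an ensemble.
#'
#' @param ensemble an `angio_ensemble`.
#' @return Data frame with `day`, `mean_mm` (across-seed mean of per-run
#'   means), `sd_mm` (across-seed SD), `n_runs`.
#' @export
ensemble_growth_curve <- function(ensemble) {
  stopifnot(inherits(ensemble, "angio_ensemble"))
  days <- ensemble$curves[[1]]$day
  m <- vapply(ensemble$curves, function(cv) cv$mean_mm, numeric(length(days)))
  data.frame(day = days,
             mean_mm = rowMeans(m),
             sd_mm = apply(m, 1, sd),
             n_runs = length(ensemble$curves))
}

# -- run directory I/O ---------------------------------------------------

#' Write or read a simulation run as plain CSV/JSON files
#'
#' `write_run()` writes `trajectories.csv` (tip_id, step, t, i, j, state),
#' `tips.csv`, `events.csv`, `measurements.csv` (vessel_id, day, extent_mm,
#' path_mm), `growth_curve.csv` and a `config.json` echo into `dir`.
#' `read_run_moves()` and `read_run_tips()` read the tables back.
#'
#' @param result an `angio_sim`.
#' @param dir output directory (created if missing).
#' @return `write_run()` returns `dir` invisibly.
#' @export
write_run <- function(result, dir) {
  stopifnot(inherits(result, "angio_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mv <- result$moves
  # move rows are 'active'; a terminated tip's last row carries its end state
  mv$state <- "active"
  last <- !duplicated(mv$tip_id, fromLast = TRUE)
  mv$state[last] <- result$tips$state[match(mv$tip_id[last], result$tips$id)]
  write.csv(mv, file.path(dir, "trajectories.csv"), row.names = FALSE)
  tips <- result$tips
  write.csv(tips, file.path(dir, "tips.csv"), row.names = FALSE)
  write.csv(result$events, file.path(dir, "events.csv"), row.names = FALSE)
  scale <- result$config$length_scale_mm
  meas <- do.call(rbind, lapply(names(result$snapshots), function(nm) {
    sn <- result$snapshots[[nm]]
    le <- .lineage_extents(sn) * scale
    pp <- tapply(sn$path, sn$root_id, sum) * scale
    data.frame(vessel_id = as.integer(names(le)), day = as.numeric(nm),
               extent_mm = as.numeric(le), path_mm = as.numeric(pp))
  }))
  write.csv(meas[order(meas$day, meas$vessel_id), ],
            file.path(dir, "measurements.csv"), row.names = FALSE)
  write.csv(as.data.frame(growth_curve(result)),
            file.path(dir, "growth_curve.csv"), row.names = FALSE)
  cfg <- result$config
  echo <- list(d = cfg$d, beta = cfg$beta, N = cfg$N, n_tips = cfg$n_tips,
               t_end = cfg$t_end, t_branching = cfg$t_branching,
               safety = cfg$safety, length_scale_mm = cfg$length_scale_mm,
               snapshot_times = cfg$snapshot_times,
               params = unclass(cfg$params), seed = result$seed)
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run_moves <- function(dir) read.csv(file.path(dir, "trajectories.csv"))

#' @rdname write_run
#' @export
read_run_tips <- function(dir) read.csv(file.path(dir, "tips.csv"))
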