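# Grand-canonical Metropolis Monte Carlo.
#
# The production engine lives in compiled code (cpp_run_chain) with its own
# deterministic RNG stream. The single-move functions below are the
# reference implementation of the move contracts - they use R's RNG and are
# meant for tests and small-scale exploration, not for production sweeps.

#' Single Metropolis displacement move (reference implementation)
#'
#' Proposes a uniform trial displacement in a cube of side
#' `2 * max_displacement` for one particle and accepts it with probability
#' `min(1, exp(-dU))`. Liquid-graft beads move in the xy-plane only; moves
#' that would take z outside `[0, h]` are rejected outright (hard
#' reflection); solid-graft beads are never selected.
#'
#' Uses R's RNG: seed with `set.seed()` for reproducibility.
#'
#' @param system A `brush_system`.
#' @param params A [simulation_parameters()] (for `max_displacement`).
#' @param i Particle index; if `NULL` one is drawn uniformly among movable
#'   particles.
#' @return List with `system` (updated), `accepted`, `dU`, `acc_prob` (the
#'   uncapped Metropolis ratio `exp(-dU)`), and `i`.
#' @export
displacement_move <- function(system, params, i = NULL) {
  movable <- which(system$mobility != 2L)
  if (length(movable) == 0) stop("no movable particles")
  if (is.null(i)) i <- movable[sample.int(length(movable), 1)]
  if (system$mobility[i] == 2L)
    stop("cannot displace a solid-graft particle")
  d <- params$max_displacement
  old <- system$positions[i, ]
  prop <- old + stats::runif(3, -d, d)
  if (system$mobility[i] == 1L) prop[3] <- old[3]
  if (prop[3] < 0 || prop[3] > system$h)
    return(list(system = system, accepted = FALSE, dU = Inf, acc_prob = 0,
                i = i))
  prop[1] <- prop[1] %% system$box[1]
  prop[2] <- prop[2] %% system$box[2]
  dU <- delta_energy(system, "displace", i = i, new_pos = prop)
  acc_prob <- exp(-dU)
  accepted <- dU <= 0 || stats::runif(1) < acc_prob
  if (accepted) system$positions[i, ] <- prop
  list(system = system, accepted = accepted, dU = dU, acc_prob = acc_prob,
       i = i)
}

#' Single grand-canonical insertion move (reference implementation)
#'
#' Proposes a solvent particle at a uniform position in the accessible
#' volume `V = Lx * Ly * h` and accepts with probability
#' `min(1, z V / (N_s + 1) * exp(-dU))`, `z` the activity and `N_s` the
#' current solvent count.
#'
#' @param system A `brush_system`.
#' @param params A [simulation_parameters()] (for `activity`).
#' @param pos Optional fixed trial position (length 3); drawn uniformly if
#'   `NULL`.
#' @return List with `system`, `accepted`, `dU`, `acc_ratio` (the uncapped
#'   acceptance ratio) and `pos`.
#' @export
insertion_move <- function(system, params, pos = NULL) {
  V <- prod(system$box) * system$h
  Ns <- nrow(system$positions) - system$n_brush
  if (is.null(pos))
    pos <- c(stats::runif(1, 0, system$box[1]),
             stats::runif(1, 0, system$box[2]),
             stats::runif(1, 0, system$h))
  dU <- delta_energy(system, "insert", new_pos = pos)
  acc_ratio <- params$activity * V / (Ns + 1) * exp(-dU)
  accepted <- acc_ratio >= 1 || stats::runif(1) < acc_ratio
  if (accepted) {
    system$positions <- rbind(system$positions, pos)
    system$species <- c(system$species, 0L)
    system$mobility <- c(system$mobility, 0L)
  }
  list(system = system, accepted = accepted, dU = dU, acc_ratio = acc_ratio,
       pos = pos)
}

#' Single grand-canonical deletion move (reference implementation)
#'
#' Removes a uniformly chosen solvent particle with probability
#' `min(1, N_s / (z V) * exp(-dU))` where `dU` is minus the particle's
#' interaction energy. Brush beads are never deleted; with no solvent
#' present the move counts as a rejected attempt.
#'
#' @param system A `brush_system`.
#' @param params A [simulation_parameters()].
#' @param i Optional index of the solvent particle to remove.
#' @return List with `system`, `accepted`, `dU`, `acc_ratio`, `i` (`NA` when
#'   no solvent exists).
#' @export
deletion_move <- function(system, params, i = NULL) {
  V <- prod(system$box) * system$h
  Ns <- nrow(system$positions) - system$n_brush
  if (Ns == 0)
    return(list(system = system, accepted = FALSE, dU = NA_real_,
                acc_ratio = 0, i = NA_integer_))
  if (is.null(i)) i <- system$n_brush + sample.int(Ns, 1)
  if (system$species[i] != 0L) stop("brush beads are never deleted")
  dU <- delta_energy(system, "delete", i = i)
  acc_ratio <- Ns / (params$activity * V) * exp(-dU)
  accepted <- acc_ratio >= 1 || stats::runif(1) < acc_ratio
  if (accepted) {
    keep <- setdiff(seq_len(nrow(system$positions)), i)
    system$positions <- system$positions[keep, , drop = FALSE]
    system$species <- system$species[keep]
    system$mobility <- system$mobility[keep]
  }
  list(system = system, accepted = accepted, dU = dU, acc_ratio = acc_ratio,
       i = i)
}

#' Run a grand-canonical Metropolis chain
#'
#' Executes `n_equilibration` then `n_production` sweeps with the compiled
#' engine. One sweep is one attempted displacement per mobile particle plus
#' a fixed number of insertion/deletion attempts (equal proposal
#' probability) equal to `gc_fraction` times the run-start solvent count -
#' frozen, because an attempt count that tracked the fluctuating count
#' would make low-occupancy states stickier and bias the grand-canonical
#' distribution. The trial displacement is auto-tuned toward 40% acceptance
#' during equilibration and frozen for production. Samples (solvent count,
#' running energy, instantaneous tip force, graft positions, density
#' histograms) are taken every `sample_interval` production sweeps.
#' Fully deterministic given `(system, params, seed)`: the engine uses its
#' own counter-seeded RNG stream and never touches R's.
#'
#' @param system A `brush_system` (see [build_system()]).
#' @param params A [simulation_parameters()]; `h` must match the system's.
#' @param record_frames Keep full position snapshots at every sample
#'   (memory-hungry; needed only for re-binning density profiles or
#'   exporting trajectories).
#' @param tune Auto-tune the displacement during equilibration
#'   (default `TRUE`).
#' @return An object of class `gcmc_run`: final `system`, `samples`
#'   data.frame (sweep, n_solvent, energy, tip_force), `stats` (attempted /
#'   accepted per move type with acceptance fractions), density histograms,
#'   graft traces, the frozen displacement, and an energy-drift diagnostic.
#' @export
run_chain <- function(system, params, record_frames = FALSE, tune = TRUE) {
  stopifnot(inherits(system, "brush_system"),
            inherits(params, "simulation_parameters"))
  if (abs(system$h - params$h) > 1e-12)
    stop("system and parameters disagree on h")
  # bonded beads get their own trial amplitude, started at roughly the
  # thermal bond-length scale of the stiffest spring present
  kmax <- if (nrow(system$bonds) > 0) max(system$bonds[, 3]) else 100
  opts <- list(
    n_equilibration = as.integer(params$n_equilibration),
    n_production = as.integer(params$n_production),
    sample_interval = as.integer(params$sample_interval),
    seed = as.numeric(params$seed),
    max_displacement = params$max_displacement,
    max_displacement_brush = min(params$max_displacement, 2 / sqrt(kmax)),
    tune = isTRUE(tune),
    activity = params$activity,
    gc_fraction = params$gc_fraction,
    bin_width = params$bin_width,
    record_frames = isTRUE(record_frames))
  out <- cpp_run_chain(unclass(system), unclass(system$interactions), opts)
  sys <- out$system
  class(sys) <- "brush_system"
  stats_df <- out$stats
  stats_df$fraction <- ifelse(stats_df$attempted > 0,
                              stats_df$accepted / stats_df$attempted, NA_real_)
  structure(
    list(system = sys, samples = out$samples, stats = stats_df,
         hist_brush = out$hist_brush, hist_solvent = out$hist_solvent,
         bin_width = out$bin_width, n_hist_samples = out$n_hist_samples,
         graft_ids = out$graft_ids, graft_trace = out$graft_trace,
         max_displacement_final = out$max_displacement_final,
         max_displacement_brush_final = out$max_displacement_brush_final,
         energy_drift = out$energy_drift,
         frames = if (record_frames) out$frames else NULL,
         h = sys$h, box = sys$box, params = params),
    class = "gcmc_run")
}

#' Calibrate the solvent activity against a target bulk density
#'
#' Finds the activity `z` at which a brush-free box of the configured fluid
#' holds the target reduced density, by secant iteration on `log z` with
#' short grand-canonical runs. Density is measured in the central slab
#' (1 rc away from either wall) so the wall depletion layers do not bias the
#' bulk estimate. In the ideal-gas limit (all amplitudes zero) the identity
#' `z = rho` is returned directly.
#'
#' @param target_density Target reduced density rho rc^3 (> 0, or 0 for the
#'   trivial z = 0).
#' @param params A [simulation_parameters()]; its interaction amplitudes and
#'   seed are used. The calibration box is brush-free.
#' @param box_xy Lateral box size for the calibration runs (rc).
#' @param h Wall separation for the calibration runs (rc).
#' @param tol Relative density tolerance (default 0.01).
#' @param max_iter Maximum secant iterations.
#' @param n_equilibration,n_production Sweep counts per iteration.
#' @return The calibrated activity, with attribute `trace` (a data.frame of
#'   the iterations: activity, measured density).
#' @export
calibrate_activity <- function(target_density, params,
                               box_xy = c(6, 6), h = 8,
                               tol = 0.01, max_iter = 12,
                               n_equilibration = 400, n_production = 1500) {
  stopifnot(target_density >= 0)
  if (target_density == 0) return(structure(0, trace = NULL))
  tab <- params$interactions
  a_ss <- tab$a[1, 1]
  ideal <- a_ss == 0 && tab$a_wall_surface == 0 && tab$a_wall_tip == 0
  if (ideal) return(structure(target_density, trace = NULL))

  measure <- function(z, seed_offset) {
    n0 <- max(1, round(target_density * prod(box_xy) * h))
    p <- params
    p$h <- h; p$box_xy <- box_xy
    p$activity <- z
    p$n_equilibration <- n_equilibration
    p$n_production <- n_production
    p$sample_interval <- 5L
    p$seed <- params$seed + seed_offset
    sys <- with_seed(p$seed, new_brush_system(
      cbind(stats::runif(n0, 0, box_xy[1]),
            stats::runif(n0, 0, box_xy[2]),
            stats::runif(n0, 0, h)),
      rep(0L, n0), rep(0L, n0), matrix(numeric(0), 0, 4),
      box_xy, h, 0L, integer(0), tab))
    run <- run_chain(sys, p)
    prof <- density_profile(run)
    core <- prof$z >= 1 & prof$z <= h - 1
    mean(prof$rho_solvent[core])
  }

  # initial guesses: ideal-gas identity and a mean-field excess term
  lz1 <- log(target_density)
  lz2 <- log(target_density) + 0.202 * a_ss * target_density
  d1 <- measure(exp(lz1), 101)
  trace <- data.frame(activity = exp(lz1), density = d1)
  if (abs(d1 - target_density) / target_density <= tol) {
    out <- exp(lz1); attr(out, "trace") <- trace; return(out)
  }
  d2 <- measure(exp(lz2), 102)
  trace <- rbind(trace, data.frame(activity = exp(lz2), density = d2))
  f1 <- log(max(d1, 1e-12) / target_density)
  f2 <- log(max(d2, 1e-12) / target_density)
  for (it in seq_len(max_iter)) {
    if (abs(f2) <= log1p(tol)) {
      out <- exp(lz2); attr(out, "trace") <- trace; return(out)
    }
    if (abs(f2 - f1) < 1e-12) break
    lz3 <- lz2 - f2 * (lz2 - lz1) / (f2 - f1)
    d3 <- measure(exp(lz3), 102 + it)
    trace <- rbind(trace, data.frame(activity = exp(lz3), density = d3))
    lz1 <- lz2; f1 <- f2
    lz2 <- lz3; f2 <- log(max(d3, 1e-12) / target_density)
  }
  if (abs(f2) <= log1p(2 * tol)) {  # accept a near-miss at twice the tol
    out <- exp(lz2); attr(out, "trace") <- trace; return(out)
  }
  stop("activity calibration did not converge; trace:\n",
       paste(utils::capture.output(print(trace)), collapse = "\n"))
}

#' @export
print.gcmc_run <- function(x, ...) {
  cat(sprintf("gcmc_run: h = %.3f rc, %d samples, %d solvent at end\n",
              x$h, nrow(x$samples),
              nrow(x$system$positions) - x$system$n_brush))
  cat(sprintf("  mean tip force %.4g kBT/rc, energy drift %.3g kBT\n",
              mean(x$samples$tip_force), x$energy_drift))
  print(x$stats)
  invisible(x)
}
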