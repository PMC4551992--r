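# System construction: grafted bead-spring chains on a triangular lattice,
# explicit solvent, plus the deterministic micro-fixtures and synthetic
# theory curves used as test ground truth.

# run `code` with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# jittered triangular lattice of n points in an Lx x Ly periodic box
graft_lattice <- function(n, Lx, Ly, jitter = 0.1) {
  nrows <- max(1L, round(sqrt(n * Ly / Lx * 2 / sqrt(3))))
  ncols <- ceiling(n / nrows)
  while (nrows * ncols < n) ncols <- ncols + 1L
  dy <- Ly / nrows
  dx <- Lx / ncols
  pts <- matrix(0, nrows * ncols, 2)
  k <- 1L
  for (r in seq_len(nrows)) {
    off <- if (r %% 2 == 0) dx / 2 else 0
    for (c in seq_len(ncols)) {
      pts[k, ] <- c((c - 1) * dx + off, (r - 0.5) * dy)
      k <- k + 1L
    }
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  pts <- pts + matrix(stats::runif(2 * n, -jitter, jitter), n, 2)
  pts[, 1] <- pts[, 1] %% Lx
  pts[, 2] <- pts[, 2] %% Ly
  pts
}

new_brush_system <- function(positions, species, mobility, bonds, box, h,
                             n_brush, chain_id, interactions, meta = list()) {
  structure(
    list(positions = positions, species = as.integer(species),
         mobility = as.integer(mobility), bonds = bonds,
         box = box, h = h, n_brush = as.integer(n_brush),
         chain_id = as.integer(chain_id), interactions = interactions,
         meta = meta),
    class = "brush_system")
}

#' Build a brush-plus-solvent system from simulation parameters
#'
#' Constructs the initial configuration: graft beads on a jittered
#' triangular lattice in the z = 0 plane (one graft per chain, populations
#' interleaved at random for multi-population brushes), chains directed
#' upward with an initial bead spacing of 0.5 rc (compressed to fit when the
#' tip is closer than the extended chain), and solvent filled uniformly to
#' the expected count for the target bulk density. Deterministic given
#' `params$seed`.
#'
#' @param params A validated [simulation_parameters()].
#' @param segregate_populations If `TRUE`, populations occupy contiguous
#'   blocks of the graft lattice instead of being interleaved.
#' @return A `brush_system`: positions (n x 3, rc), species (0 = solvent,
#'   k = brush population k), mobility (0 free, 1 liquid graft, 2 solid
#'   graft), bonds (i, j, kappa, r0), box, h, chain ids and the interaction
#'   table.
#' @export
build_system <- function(params, segregate_populations = FALSE) {
  validate_parameters(params)
  pops <- params$architecture$populations
  counts <- chain_counts(params$architecture, params$area_nm2)
  n_chains <- sum(counts)
  Lx <- params$box_xy[1]; Ly <- params$box_xy[2]; h <- params$h
  r0 <- params$bond_rest_length
  # initial bead spacing: the thermal mean bond length of the spring (the
  # mean of p(r) ~ r^2 exp(-kappa (r-r0)^2 / 2) at r0 = 0 is 2 sqrt(2/(pi
  # kappa))), capped at 0.5 rc. Starting at a fixed 0.5 rc would leave
  # stiff chains (kappa = 2000) with enormous initial bond energies and a
  # collapse distance they cannot cover within any reasonable equilibration.
  spacing_of <- function(kappa)
    if (r0 > 0) r0 else min(0.5, 2 * sqrt(2 / (pi * kappa)))
  graft_mob <- if (params$architecture$mobility == "liquid") 1L else 2L

  with_seed(params$seed, {
    grafts <- graft_lattice(n_chains, Lx, Ly, params$graft_jitter)
    pop_of_chain <- rep(seq_along(counts), counts)
    if (!segregate_populations && length(counts) > 1)
      pop_of_chain <- sample(pop_of_chain)

    n_beads <- sum(pops$N[pop_of_chain])
    pos <- matrix(0, n_beads, 3)
    species <- integer(n_beads)
    mobility <- integer(n_beads)
    chain_id <- integer(n_beads)
    bonds <- matrix(0, n_beads - n_chains, 4)
    bead <- 0L; bnd <- 0L
    compressed <- FALSE
    for (c in seq_len(n_chains)) {
      p <- pop_of_chain[c]
      N <- pops$N[p]
      dz <- spacing_of(pops$kappa[p])
      if ((N - 1) * dz > h - 0.1) {
        dz <- (h - 0.1) / max(1, N - 1)
        compressed <- TRUE
      }
      for (j in seq_len(N)) {
        bead <- bead + 1L
        pos[bead, ] <- c(grafts[c, 1], grafts[c, 2], (j - 1) * dz)
        species[bead] <- p
        mobility[bead] <- if (j == 1) graft_mob else 0L
        chain_id[bead] <- c
        if (j > 1) {
          bnd <- bnd + 1L
          bonds[bnd, ] <- c(bead - 1L, bead, pops$kappa[p], r0)
        }
      }
    }
    if (compressed)
      warning("chains longer than the gap: initial conformations compressed")

    n_solv <- max(0, round(params$target_density * Lx * Ly * h) - n_beads)
    if (n_solv > 0) {
      solv <- cbind(stats::runif(n_solv, 0, Lx),
                    stats::runif(n_solv, 0, Ly),
                    stats::runif(n_solv, 0, h))
      pos <- rbind(pos, solv)
    }
    species <- c(species, rep(0L, n_solv))
    mobility <- c(mobility, rep(0L, n_solv))

    new_brush_system(
      pos, species, mobility, bonds, c(Lx, Ly), h,
      n_brush = n_beads, chain_id = chain_id,
      interactions = params$interactions,
      meta = list(seed = params$seed,
                  mobility_class = params$architecture$mobility,
                  populations = pops, counts = counts,
                  pop_of_chain = pop_of_chain))
  })
}

#' Build the uniform-brush (normal cell) system
#'
#' 16 chains of 27 beads at the default cell area, plus solvent.
#'
#' @param params A [simulation_parameters()] whose architecture is the
#'   normal preset (the default).
#' @return A `brush_system`.
#' @export
build_normal_system <- function(params = simulation_parameters()) {
  if (nrow(params$architecture$populations) != 1)
    stop("normal preset has a single population; see build_cancer_system")
  build_system(params)
}

#' Build the three-length-brush (cancerous cell) system
#'
#' 36 + 10 + 4 chains of N = 5, 30, 42 beads; all bonds get kappa = 100
#' (soft) or kappa = 2000 (stiff).
#'
#' @param params A [simulation_parameters()]; its architecture is replaced
#'   by the cancer preset with the requested stiffness if it is not already
#'   a three-population brush.
#' @param stiffness `"soft"` or `"stiff"`.
#' @param segregate_populations See [build_system()].
#' @return A `brush_system`.
#' @export
build_cancer_system <- function(params = simulation_parameters(
                                  architecture = cancer_architecture()),
                                stiffness = c("soft", "stiff"),
                                segregate_populations = FALSE) {
  stiffness <- match.arg(stiffness)
  arch <- params$architecture
  if (nrow(arch$populations) != 3 ||
      !isTRUE(all.equal(arch$populations$N, c(5, 30, 42)))) {
    params$architecture <- cancer_architecture(stiffness, arch$mobility)
    params$interactions <- interaction_table(
      n_populations = 3,
      a_same = params$interactions$a[1, 1],
      a_solvent_brush = if (ncol(params$interactions$a) > 1)
        params$interactions$a[1, 2] else params$interactions$a[1, 1] + 3,
      a_wall_surface = params$interactions$a_wall_surface,
      a_wall_tip = params$interactions$a_wall_tip,
      exclude_bonded = params$interactions$exclude_bonded)
  } else {
    kappa <- if (stiffness == "soft") 100 else 2000
    params$architecture$populations$kappa <- kappa
  }
  build_system(params, segregate_populations = segregate_populations)
}

#' Deterministic micro-fixtures with hand-computed energies
#'
#' A small catalogue of configurations whose energy breakdown is known in
#' closed form; they are the ground truth of the energy tests. The expected
#' values are computed from the potential formulas by hand-checkable
#' arithmetic, never by the engine.
#'
#' @param name One of `"single-pair"`, `"single-chain-3"`, `"wall-contact"`,
#'   `"cross-boundary-pair"`, `"two-chain-interdigitated"`.
#' @return A list with `system` (a `brush_system`), `expected` (named list
#'   pair/bond/wall_surface/wall_tip/total, kBT) and `description`.
#' @export
make_micro_fixture <- function(name) {
  tab1 <- interaction_table(n_populations = 1)
  box <- c(7, 7); h <- 12
  no_bonds <- matrix(numeric(0), 0, 4)
  fx <- switch(name,
    "single-pair" = {
      pos <- rbind(c(2, 2, 2), c(2.5, 2, 2))
      sys <- new_brush_system(pos, c(0L, 0L), c(0L, 0L), no_bonds,
                              box, h, 0L, integer(0), tab1)
      list(system = sys,
           expected = list(pair = 12.5 * 0.25, bond = 0,
                           wall_surface = 0, wall_tip = 0),
           description = "two solvent beads at r = 0.5 rc, far from walls")
    },
    "wall-contact" = {
      pos <- rbind(c(2, 2, 0))
      sys <- new_brush_system(pos, 0L, 0L, no_bonds,
                              box, h, 0L, integer(0), tab1)
      list(system = sys,
           expected = list(pair = 0, bond = 0,
                           wall_surface = 12.5, wall_tip = 0),
           description = "one solvent bead at zero gap from the surface wall")
    },
    "single-chain-3" = {
      pos <- rbind(c(3, 3, 0), c(3, 3, 0.1), c(3, 3, 0.2))
      bonds <- rbind(c(1, 2, 100, 0), c(2, 3, 100, 0))
      sys <- new_brush_system(pos, c(1L, 1L, 1L), c(1L, 0L, 0L), bonds,
                              box, h, 3L, c(1L, 1L, 1L), tab1)
      # bonds: 2 x (100/2) 0.1^2 = 1; pairs: 2 x 12.5 * 0.9^2 + 12.5 * 0.8^2;
      # surface wall on the two non-graft beads at z = 0.1, 0.2
      list(system = sys,
           expected = list(pair = 2 * 12.5 * 0.81 + 12.5 * 0.64,
                           bond = 1.0,
                           wall_surface = 12.5 * 0.81 + 12.5 * 0.64,
                           wall_tip = 0),
           description = "3-bead chain, beads 0.1 rc apart, kappa = 100")
    },
    "cross-boundary-pair" = {
      pos <- rbind(c(0.1, 1, 2), c(6.9, 1, 2))
      sys <- new_brush_system(pos, c(0L, 0L), c(0L, 0L), no_bonds,
                              box, h, 0L, integer(0), tab1)
      list(system = sys,
           expected = list(pair = 12.5 * 0.8^2, bond = 0,
                           wall_surface = 0, wall_tip = 0),
           description = "pair at minimum-image distance 0.2 rc across x")
    },
    "two-chain-interdigitated" = {
      pos <- rbind(c(1, 1, 0), c(1, 1, 0.5),
                   c(1.3, 1, 0), c(1.3, 1, 0.5))
      bonds <- rbind(c(1, 2, 100, 0), c(3, 4, 100, 0))
      sys <- new_brush_system(pos, rep(1L, 4), c(1L, 0L, 1L, 0L), bonds,
                              box, h, 4L, c(1L, 1L, 2L, 2L), tab1)
      rdiag <- sqrt(0.3^2 + 0.5^2)
      list(system = sys,
           expected = list(
             pair = 2 * 12.5 * 0.5^2 + 2 * 12.5 * 0.7^2 +
               2 * 12.5 * (1 - rdiag)^2,
             bond = 2 * 0.5 * 100 * 0.25,
             wall_surface = 2 * 12.5 * 0.25,
             wall_tip = 0),
           description = "two 2-bead chains 0.3 rc apart, all pairs in range")
    },
    stop("unknown fixture name: ", name)
  )
  fx$expected$total <- fx$expected$pair + fx$expected$bond +
    fx$expected$wall_surface + fx$expected$wall_tip
  fx$name <- name
  fx
}

#' Catalogue of micro-fixture names
#' @return Character vector of valid [make_micro_fixture()] names.
#' @export
micro_fixture_names <- function() {
  c("single-pair", "wall-contact", "single-chain-3",
    "cross-boundary-pair", "two-chain-interdigitated")
}

#' Specification of a synthetic theory force curve
#'
#' Describes a noisy multi-population Alexander-de Gennes force-distance
#' curve used to exercise the fitting layer: population brush lengths and
#' grafting densities, a separation grid, and seeded multiplicative noise.
#'
#' @param populations Data.frame with columns `L` (uncompressed brush length,
#'   rc) and `Gamma` (grafting density, rc^-2).
#' @param h_grid Strictly increasing separations in rc, all positive.
#' @param noise_sd Relative (multiplicative) Gaussian noise level, >= 0.
#' @param seed Integer seed for the noise realization.
#' @return An object of class `synthetic_curve_spec`.
#' @export
synthetic_curve_spec <- function(populations, h_grid, noise_sd = 0, seed = 1) {
  stopifnot(is.data.frame(populations),
            all(c("L", "Gamma") %in% names(populations)),
            all(populations$L > 0), all(populations$Gamma > 0),
            noise_sd >= 0)
  if (any(h_grid <= 0)) stop("all separations must be positive")
  if (any(diff(h_grid) <= 0)) stop("h_grid must be strictly increasing")
  structure(list(populations = populations, h_grid = h_grid,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_curve_spec")
}

#' Generate a synthetic force-distance table
#'
#' Evaluates the multi-population Alexander-de Gennes sphere force on the
#' spec's separation grid and applies seeded multiplicative Gaussian noise.
#' The true populations are attached as metadata so parameter-recovery tests
#' can compare fitted against generating values.
#'
#' @param spec A [synthetic_curve_spec()].
#' @return A data.frame with columns `h` (rc) and `F_over_R` (kBT/rc^2),
#'   with attribute `truth` holding the generating spec.
#' @export
synth_force_curve <- function(spec) {
  stopifnot(inherits(spec, "synthetic_curve_spec"))
  pops <- lapply(seq_len(nrow(spec$populations)), function(i)
    brush_population(L = spec$populations$L[i],
                     Gamma = spec$populations$Gamma[i]))
  f <- multi_brush_force(spec$h_grid, pops)
  if (spec$noise_sd > 0)
    f <- with_seed(spec$seed,
                   f * (1 + stats::rnorm(length(f), 0, spec$noise_sd)))
  out <- data.frame(h = spec$h_grid, F_over_R = f)
  attr(out, "truth") <- spec
  out
}

#' @export
print.brush_system <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf(
    "brush_system: %d particles (%d brush in %d chains, %d solvent)\n",
    n, x$n_brush, length(unique(x$chain_id)), n - x$n_brush))
  cat(sprintf("  box %.3f x %.3f rc, h = %.3f rc, grafts %s\n",
              x$box[1], x$box[2], x$h,
              if (any(x$mobility == 2L)) "solid" else "liquid"))
  invisible(x)
}
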