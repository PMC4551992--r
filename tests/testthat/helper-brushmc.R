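# Shared helpers: a pure-R brute-force energy oracle (independent of the
# compiled path), small system factories, and fake observable objects.

# O(N^2) energy oracle in plain R; mirrors the model definition, not the
# engine implementation.
r_total_energy <- function(system, interactions = system$interactions) {
  pos <- system$positions
  n <- nrow(pos)
  Lx <- system$box[1]; Ly <- system$box[2]; h <- system$h
  a <- interactions$a
  sp <- system$species + 1L
  ep <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- pos[i, 1] - pos[j, 1]; dx <- dx - Lx * round(dx / Lx)
      dy <- pos[i, 2] - pos[j, 2]; dy <- dy - Ly * round(dy / Ly)
      dz <- pos[i, 3] - pos[j, 3]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      if (r < 1) ep <- ep + 0.5 * a[sp[i], sp[j]] * (1 - r)^2
    }
  }
  eb <- 0
  if (nrow(system$bonds) > 0) {
    for (b in seq_len(nrow(system$bonds))) {
      i <- system$bonds[b, 1]; j <- system$bonds[b, 2]
      dx <- pos[i, 1] - pos[j, 1]; dx <- dx - Lx * round(dx / Lx)
      dy <- pos[i, 2] - pos[j, 2]; dy <- dy - Ly * round(dy / Ly)
      dz <- pos[i, 3] - pos[j, 3]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      eb <- eb + 0.5 * system$bonds[b, 3] * (r - system$bonds[b, 4])^2
    }
  }
  free <- system$mobility == 0L
  ws <- sum(ifelse(free & pos[, 3] < 1,
                   0.5 * interactions$a_wall_surface * (1 - pos[, 3])^2, 0))
  gap <- h - pos[, 3]
  wt <- sum(ifelse(gap < 1, 0.5 * interactions$a_wall_tip * (1 - gap)^2, 0))
  if (isTRUE(interactions$exclude_bonded) && nrow(system$bonds) > 0) {
    for (b in seq_len(nrow(system$bonds))) {
      i <- system$bonds[b, 1]; j <- system$bonds[b, 2]
      dx <- pos[i, 1] - pos[j, 1]; dx <- dx - Lx * round(dx / Lx)
      dy <- pos[i, 2] - pos[j, 2]; dy <- dy - Ly * round(dy / Ly)
      dz <- pos[i, 3] - pos[j, 3]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      if (r < 1) ep <- ep - 0.5 * a[sp[i], sp[j]] * (1 - r)^2
    }
  }
  list(pair = ep, bond = eb, wall_surface = ws, wall_tip = wt,
       total = ep + eb + ws + wt)
}

# random solvent-only system
random_fluid <- function(n, box = c(7, 7), h = 5, seed = 1,
                         interactions = interaction_table(1)) {
  set.seed(seed)
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, h))
  brushmc:::new_brush_system(pos, rep(0L, n), rep(0L, n),
                             matrix(numeric(0), 0, 4), box, h, 0L,
                             integer(0), interactions)
}

# small bonded system: a few short grafted chains plus solvent
random_chain_system <- function(seed = 1, h = 6, n_solvent = 30,
                                kappa = 100, mobility = "liquid") {
  arch <- brush_architecture(
    data.frame(N = 4, Gamma = 0.25, kappa = kappa), mobility = mobility)
  p <- simulation_parameters(architecture = arch, h = h, seed = seed,
                             target_density = 0)
  sys <- build_system(p)
  if (n_solvent > 0) {
    set.seed(seed + 1)
    solv <- cbind(runif(n_solvent, 0, sys$box[1]),
                  runif(n_solvent, 0, sys$box[2]),
                  runif(n_solvent, 0, h))
    sys$positions <- rbind(sys$positions, solv)
    sys$species <- c(sys$species, rep(0L, n_solvent))
    sys$mobility <- c(sys$mobility, rep(0L, n_solvent))
  }
  sys
}

# ideal-gas parameter/system pair (all amplitudes zero)
ideal_gas_setup <- function(n0 = 20, box = c(3, 3), h = 3, zV = 20,
                            seed = 1) {
  tab <- interaction_table(1, a_same = 0, a_solvent_brush = 0,
                           a_wall_surface = 0, a_wall_tip = 0)
  V <- prod(box) * h
  set.seed(seed)
  sys <- brushmc:::new_brush_system(
    cbind(runif(n0, 0, box[1]), runif(n0, 0, box[2]), runif(n0, 0, h)),
    rep(0L, n0), rep(0L, n0), matrix(numeric(0), 0, 4), box, h, 0L,
    integer(0), tab)
  p <- simulation_parameters(interactions = tab, h = h, activity = zV / V,
                             gc_fraction = 1, seed = seed)
  p$box_xy <- box
  list(system = sys, params = p, V = V)
}

# hand-built density profile object for estimator tests
fake_density_profile <- function(z, rho_brush, rho_solvent, area, h,
                                 bin_width) {
  out <- data.frame(z = z, rho_brush = rho_brush, rho_solvent = rho_solvent)
  attr(out, "area") <- area
  attr(out, "h") <- h
  attr(out, "bin_width") <- bin_width
  attr(out, "n_samples") <- 1
  class(out) <- c("density_profile", "data.frame")
  out
}

# minimal fake gcmc_run for force_profile tests
fake_run <- function(h, forces, box = c(7, 7)) {
  structure(list(h = h, box = box,
                 samples = data.frame(sweep = seq_along(forces),
                                      n_solvent = 0, energy = 0,
                                      tip_force = forces)),
            class = "gcmc_run")
}
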