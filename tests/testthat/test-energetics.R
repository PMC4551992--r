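test_that("potential formulas give the closed-form values", {
  # pair: cutoff, full overlap, midpoint
  expect_equal(pair_potential(1.0, 37), 0)
  expect_equal(pair_potential(1.5, 25), 0)
  expect_equal(pair_potential(0, 25), 12.5)
  expect_equal(pair_potential(0.5, 25), 3.125)
  expect_error(pair_potential(-0.1, 25))

  # bond: rest length, soft and stiff values, exact factor 20
  expect_equal(bond_potential(0.3, 100, r0 = 0.3), 0)
  expect_equal(bond_potential(0.1, 100), 0.5)
  expect_equal(bond_potential(0.1, 2000), 10.0)
  expect_identical(bond_potential(0.1, 2000) / bond_potential(0.1, 100), 20)

  # wall: cutoff, contact, penetration
  expect_equal(wall_potential(1, 25), 0)
  expect_equal(wall_potential(0, 25), 12.5)
  expect_equal(wall_potential(-0.2, 25), 18.0)
})

test_that("micro-fixtures match their hand-computed energies to 1e-10", {
  for (nm in micro_fixture_names()) {
    fx <- make_micro_fixture(nm)
    e <- total_energy(fx$system)
    expect_equal(e$pair, fx$expected$pair, tolerance = 1e-12, info = nm)
    expect_equal(e$bond, fx$expected$bond, tolerance = 1e-12, info = nm)
    expect_equal(e$wall_surface, fx$expected$wall_surface,
                 tolerance = 1e-12, info = nm)
    expect_equal(e$wall_tip, fx$expected$wall_tip,
                 tolerance = 1e-12, info = nm)
    expect_lt(abs(e$total - fx$expected$total), 1e-10)
    expect_lt(abs(e$total - (e$pair + e$bond + e$wall_surface + e$wall_tip)),
              1e-10 * max(1, abs(e$total)))
  }
  expect_error(make_micro_fixture("no-such-fixture"), "unknown")
})

test_that("engine total energy matches the pure-R brute-force oracle", {
  for (seed in 1:3) {
    sys <- random_fluid(60, seed = seed)
    e <- total_energy(sys)
    o <- r_total_energy(sys)
    expect_equal(e$total, o$total, tolerance = 1e-12)
    expect_equal(e$pair, o$pair, tolerance = 1e-12)
  }
  # bonded + grafted system, both bonded-pair conventions
  sys <- random_chain_system(seed = 4)
  expect_equal(total_energy(sys)$total, r_total_energy(sys)$total,
               tolerance = 1e-12)
  sys$interactions$exclude_bonded <- TRUE
  expect_equal(total_energy(sys)$total, r_total_energy(sys)$total,
               tolerance = 1e-12)
})

test_that("all potentials non-negative; totals non-negative", {
  for (seed in 1:5) {
    sys <- random_fluid(40, h = 3, seed = seed)
    e <- total_energy(sys)
    expect_gte(e$pair, 0); expect_gte(e$bond, 0)
    expect_gte(e$wall_surface, 0); expect_gte(e$wall_tip, 0)
    expect_gte(e$total, 0)
  }
})

test_that("incremental delta energy equals full recompute", {
  sys <- random_chain_system(seed = 11, n_solvent = 8)  # ~20 particles
  set.seed(99)
  for (k in 1:200) {
    i <- sample(nrow(sys$positions), 1)
    if (sys$mobility[i] == 2L) next
    np <- sys$positions[i, ] + runif(3, -0.5, 0.5)
    np[3] <- min(max(np[3], 0), sys$h)
    if (sys$mobility[i] == 1L) np[3] <- sys$positions[i, 3]
    dU <- delta_energy(sys, "displace", i = i, new_pos = np)
    after <- sys
    after$positions[i, ] <- c(np[1] %% sys$box[1], np[2] %% sys$box[2], np[3])
    dU_full <- total_energy(after)$total - total_energy(sys)$total
    expect_lt(abs(dU - dU_full), 1e-10)
    sys <- after  # random walk through configuration space
  }
})

test_that("insertion/deletion deltas match explicit recomputation", {
  sys <- random_fluid(30, seed = 21)
  set.seed(5)
  for (k in 1:20) {
    pos <- c(runif(1, 0, 7), runif(1, 0, 7), runif(1, 0, 5))
    dU <- delta_energy(sys, "insert", new_pos = pos)
    after <- sys
    after$positions <- rbind(after$positions, pos)
    after$species <- c(after$species, 0L)
    after$mobility <- c(after$mobility, 0L)
    expect_lt(abs(dU - (total_energy(after)$total - total_energy(sys)$total)),
              1e-10)
    i <- sample(nrow(sys$positions), 1)
    dUd <- delta_energy(sys, "delete", i = i)
    afterd <- sys
    keep <- setdiff(seq_len(nrow(sys$positions)), i)
    afterd$positions <- afterd$positions[keep, , drop = FALSE]
    afterd$species <- afterd$species[keep]
    afterd$mobility <- afterd$mobility[keep]
    expect_lt(abs(dUd - (total_energy(afterd)$total -
                           total_energy(sys)$total)), 1e-10)
  }
})

test_that("null move and isolated deletion give zero delta", {
  sys <- random_fluid(20, seed = 31)
  expect_equal(delta_energy(sys, "displace", i = 3,
                            new_pos = sys$positions[3, ]), 0)
  # a bead far from everything (and > 1 rc from both walls)
  iso <- sys
  iso$positions <- rbind(iso$positions, c(3.5, 3.5, 2.5))
  iso$positions[, 1] <- c(rep(0.5, 20), 3.5)  # crowd others away
  iso$positions[, 2] <- c(rep(0.5, 20), 3.5)
  iso$species <- c(sys$species, 0L)
  iso$mobility <- c(sys$mobility, 0L)
  expect_equal(delta_energy(iso, "delete", i = 21), 0)
})

test_that("solid grafts cannot be displaced or deleted", {
  sys <- random_chain_system(seed = 41, mobility = "solid")
  g <- which(sys$mobility == 2L)[1]
  expect_error(delta_energy(sys, "displace", i = g, new_pos = c(1, 1, 0)),
               "solid")
  expect_error(delta_energy(sys, "delete", i = 1), "solvent")
})

test_that("cell list enumerates exactly the all-pairs set", {
  for (seed in 1:5) {
    sys <- random_fluid(50, seed = seed)
    p_cell <- build_cell_list(sys, "cell")
    p_all <- build_cell_list(sys, "all")
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(p_cell), key(p_all))
  }
  # single bead: empty
  sys1 <- random_fluid(1, seed = 1)
  expect_equal(nrow(build_cell_list(sys1)), 0)
  # boundary pair at distance just under the cutoff across the periodic seam
  sysb <- random_fluid(2, seed = 1)
  sysb$positions[1, ] <- c(0.05, 1, 2)
  sysb$positions[2, ] <- c(7 - (1 - 1e-9) + 0.05, 1, 2)
  expect_equal(nrow(build_cell_list(sysb, "cell")), 1)
  # small box: falls back to all-pairs and still agrees
  syss <- random_fluid(12, box = c(2.5, 2.5), h = 2, seed = 3)
  expect_identical(nrow(build_cell_list(syss, "cell")),
                   nrow(build_cell_list(syss, "all")))
})

test_that("energy is invariant under rigid xy translation", {
  sys <- random_chain_system(seed = 51, n_solvent = 40)
  e0 <- total_energy(sys)$total
  for (shift in list(c(1.23, -2.1), c(3.7, 0.4))) {
    moved <- sys
    moved$positions[, 1] <- (moved$positions[, 1] + shift[1]) %% sys$box[1]
    moved$positions[, 2] <- (moved$positions[, 2] + shift[2]) %% sys$box[2]
    expect_lt(abs(total_energy(moved)$total - e0), 1e-9)
  }
})
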