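test_that("displacement move honors the Metropolis rule and constraints", {
  p <- simulation_parameters(h = 5)
  # a lone particle far from walls: dU = 0, always accepted
  sys <- random_fluid(1, h = 5, seed = 1)
  sys$positions[1, ] <- c(3.5, 3.5, 2.5)
  set.seed(1)
  mv <- displacement_move(sys, p, i = 1)
  expect_true(mv$accepted)
  expect_equal(mv$dU, 0)

  # z outside [0, h] is rejected outright (hard reflection)
  sys$positions[1, 3] <- 0.01
  p2 <- p; p2$max_displacement <- 5
  set.seed(2)
  rejected <- FALSE
  for (k in 1:20) {
    mv <- displacement_move(sys, p2, i = 1)
    if (!mv$accepted && is.infinite(mv$dU)) { rejected <- TRUE; break }
    sys <- mv$system; sys$positions[1, 3] <- 0.01
  }
  expect_true(rejected)

  # liquid grafts keep z; solid grafts are never movable
  ch <- random_chain_system(seed = 3, n_solvent = 0)
  g <- which(ch$mobility == 1L)[1]
  set.seed(3)
  mv <- displacement_move(ch, p, i = g)
  expect_equal(mv$system$positions[g, 3], ch$positions[g, 3])
  chs <- random_chain_system(seed = 3, mobility = "solid", n_solvent = 0)
  gs <- which(chs$mobility == 2L)[1]
  expect_error(displacement_move(chs, p, i = gs), "solid")
})

test_that("insertion and deletion acceptance ratios follow the GC formulas", {
  sys <- random_fluid(10, h = 5, seed = 7)
  p <- simulation_parameters(h = 5, activity = 2.5)
  V <- prod(sys$box) * sys$h
  pos <- c(2, 2, 2.5)
  dU <- delta_energy(sys, "insert", new_pos = pos)
  set.seed(1)
  mv <- insertion_move(sys, p, pos = pos)
  expect_equal(mv$acc_ratio, 2.5 * V / 11 * exp(-dU), tolerance = 1e-12)

  # deletion of the sole particle in an ideal box at large z: ratio 1/(zV)
  ig <- ideal_gas_setup(n0 = 1, zV = 50)
  set.seed(1)
  dm <- deletion_move(ig$system, ig$params, i = 1)
  expect_equal(dm$acc_ratio, 1 / 50, tolerance = 1e-12)

  # no solvent present: rejected attempt, not an error
  empty <- ig$system
  empty$positions <- empty$positions[0, , drop = FALSE]
  empty$species <- integer(0); empty$mobility <- integer(0)
  dm0 <- deletion_move(empty, ig$params)
  expect_false(dm0$accepted)
  expect_equal(dm0$acc_ratio, 0)

  # z = 0: insertion never accepted
  p0 <- p; p0$activity <- 0
  set.seed(2)
  for (k in 1:10) expect_false(insertion_move(sys, p0)$accepted)
})

test_that("insert-then-delete satisfies detailed-balance reciprocity", {
  set.seed(17)
  for (k in 1:20) {
    sys <- random_fluid(sample(3:25, 1), h = 4, seed = k)
    p <- simulation_parameters(h = 4, activity = runif(1, 0.5, 10))
    pos <- c(runif(1, 0, 7), runif(1, 0, 7), runif(1, 0, 4))
    ins <- insertion_move(sys, p, pos = pos)
    if (!ins$accepted) next
    n_new <- nrow(ins$system$positions)
    del <- deletion_move(ins$system, p, i = n_new)
    expect_equal(del$dU, -ins$dU, tolerance = 1e-10)
    expect_equal(ins$acc_ratio * del$acc_ratio, 1, tolerance = 1e-10)
  }
})

test_that("ideal-gas limit reproduces the grand-canonical density", {
  ig <- ideal_gas_setup(zV = 20, seed = 5)
  p <- ig$params
  p$n_equilibration <- 200; p$n_production <- 20000; p$sample_interval <- 10
  run <- run_chain(ig$system, p)
  m <- mean(run$samples$n_solvent)
  v <- var(run$samples$n_solvent)
  expect_lt(abs(m - 20), 0.5)          # ~5 sigma of the mean estimate
  expect_lt(abs(v - 20) / 20, 0.15)    # Poisson: Var(N) = <N>
  # solvent count fluctuates: grand-canonical signature
  expect_gt(length(unique(run$samples$n_solvent)), 5)
})

test_that("run_chain schedule arithmetic and determinism contracts hold", {
  ig <- ideal_gas_setup(zV = 10, seed = 9)
  p <- ig$params
  p$n_equilibration <- 50; p$n_production <- 10000; p$sample_interval <- 100
  run <- run_chain(ig$system, p)
  expect_equal(nrow(run$samples), 100)   # the meandering-figure schedule

  p$n_production <- 0
  run0 <- run_chain(ig$system, p)
  expect_equal(nrow(run0$samples), 0)

  # bit-identical re-runs
  p$n_production <- 500; p$sample_interval <- 10
  r1 <- run_chain(ig$system, p)
  r2 <- run_chain(ig$system, p)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$system$positions, r2$system$positions)

  # different seed, different trajectory
  p2 <- p; p2$seed <- p$seed + 1
  r3 <- run_chain(ig$system, p2)
  expect_false(identical(r1$system$positions, r3$system$positions))
})

test_that("graft constraints hold through a run", {
  arch <- brush_architecture(data.frame(N = 5, Gamma = 0.3, kappa = 100),
                             mobility = "liquid")
  p <- simulation_parameters(architecture = arch, h = 6, seed = 12,
                             n_equilibration = 100, n_production = 400,
                             sample_interval = 10)
  sys <- build_system(p)
  run <- run_chain(sys, p)
  g <- which(sys$mobility == 1L)
  # liquid grafts: z bit-identical, xy moved
  expect_identical(run$system$positions[g, 3], sys$positions[g, 3])
  expect_false(all(run$system$positions[g, 1] == sys$positions[g, 1]))

  arch2 <- brush_architecture(data.frame(N = 5, Gamma = 0.3, kappa = 100),
                              mobility = "solid")
  p2 <- simulation_parameters(architecture = arch2, h = 6, seed = 12,
                              n_equilibration = 100, n_production = 400,
                              sample_interval = 10)
  sys2 <- build_system(p2)
  run2 <- run_chain(sys2, p2)
  g2 <- which(sys2$mobility == 2L)
  expect_identical(run2$system$positions[g2, ], sys2$positions[g2, ])
})

test_that("displacement acceptance is tuned into the target band", {
  p <- simulation_parameters(h = 6, seed = 13, n_equilibration = 600,
                             n_production = 600, sample_interval = 10,
                             architecture = brush_architecture(
                               data.frame(N = 8, Gamma = 0.3, kappa = 100)))
  sys <- build_system(p)
  run <- run_chain(sys, p)
  fr <- run$stats$fraction[run$stats$move == "displace_free"]
  expect_gt(fr, 0.2)
  expect_lt(fr, 0.7)
})

test_that("activity calibration has the analytic limits", {
  p <- simulation_parameters()
  expect_equal(as.numeric(calibrate_activity(0, p)), 0)
  ig <- ideal_gas_setup()
  expect_equal(as.numeric(calibrate_activity(3, ig$params)), 3)
})
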