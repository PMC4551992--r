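test_that("tip force is the wall-normal derivative sum", {
  sys <- random_fluid(1, h = 5, seed = 1)
  sys$positions[1, ] <- c(3, 3, 2)      # > 1 rc from the tip
  expect_equal(tip_force(sys), 0)
  sys$positions[1, 3] <- 5              # contact
  expect_equal(tip_force(sys), 25)
  sys$positions[1, 3] <- 4.5            # half range
  expect_equal(tip_force(sys), 12.5)
  expect_gte(tip_force(sys), 0)
})

test_that("force profiles aggregate means, errors, and the baseline", {
  r1 <- fake_run(4, rep(7, 40))
  r2 <- fake_run(8, rep(2, 40))
  prof <- force_profile(list(r2, r1), baseline = "none")
  expect_equal(prof$h_rc, c(4, 8))      # sorted ascending
  expect_equal(prof$F, c(7, 2))
  expect_equal(prof$SE, c(0, 0))        # constant streams
  expect_equal(prof$P, c(7, 2) / 49)

  # largest-h baseline: uncompressed reference is subtracted everywhere
  profb <- force_profile(list(r1, r2))
  expect_equal(profb$F, c(5, 0))

  expect_error(force_profile(list(fake_run(4, 3), fake_run(8, c(1, 2)))),
               "uncertainty")
  expect_error(force_profile(list(r1)))
})

test_that("normalized profiles have unit maxima and are idempotent", {
  cv <- data.frame(h = c(2, 4, 8), F = c(10, 4, 1))
  n1 <- normalize_curve(cv)
  expect_equal(max(n1$h), 1)
  expect_equal(max(n1$F), 1)
  n2 <- normalize_curve(n1)
  expect_equal(n2, n1, tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(normalize_curve(data.frame(h = c(1, 2), F = c(0, 0))),
               "positive")
})

test_that("Derjaguin transform integrates the pressure tail", {
  mk_prof <- function(h, P) {
    out <- data.frame(h_rc = h, h_nm = h * 0.646, F = P * 49, SE = 0,
                      P = P, n_samples = 10)
    attr(out, "area") <- 49
    class(out) <- c("force_profile", "data.frame")
    out
  }
  # P identically zero
  p0 <- derjaguin_transform(mk_prof(1:5, rep(0, 5)))
  expect_equal(p0$F_over_R, rep(0, 5))
  # constant pressure: F/R = 2 pi c (h_max - h)
  h <- seq(2, 6, by = 0.5)
  pc <- suppressWarnings(derjaguin_transform(mk_prof(h, rep(3, length(h)))))
  expect_equal(pc$F_over_R, 2 * pi * 3 * (max(h) - h), tolerance = 1e-12)
  # warns when the tail is not reached
  expect_warning(derjaguin_transform(mk_prof(h, rep(3, length(h)))), "tail")

  # AdG pressure input reproduces the closed-form sphere force to < 1%
  pop <- brush_population(L = 10, s = 1)
  hg <- seq(1, 20.5, length.out = 200)
  prof <- mk_prof(hg, adg_pressure(hg, pop))
  tr <- derjaguin_transform(prof)
  ref <- adg_sphere_force(hg, pop)
  sel <- ref > max(ref) * 1e-3
  expect_lt(max(abs(tr$F_over_R[sel] - ref[sel]) / ref[sel]), 0.01)
})

test_that("density profiles conserve particle counts", {
  # brush-only canonical run: integral must equal the bead count exactly
  arch <- brush_architecture(data.frame(N = 6, Gamma = 0.4, kappa = 100))
  p <- simulation_parameters(architecture = arch, h = 8, seed = 2,
                             target_density = 0, gc_fraction = 0,
                             n_equilibration = 50, n_production = 200,
                             sample_interval = 10)
  sys <- build_system(p)
  run <- run_chain(sys, p)
  prof <- density_profile(run)
  area <- attr(prof, "area"); bw <- attr(prof, "bin_width")
  expect_equal(sum(prof$rho_brush) * area * bw, sys$n_brush,
               tolerance = 1e-9)
  expect_error(density_profile(run, bin_width = -1), "positive")

  # uniform ideal gas: flat profile at N/(A h) within counting error
  ig <- ideal_gas_setup(n0 = 200, box = c(5, 5), h = 4, zV = 200, seed = 4)
  pig <- ig$params
  pig$n_equilibration <- 100; pig$n_production <- 2000
  pig$sample_interval <- 5
  rig <- run_chain(ig$system, pig)
  pr <- density_profile(rig)
  expected <- mean(rig$samples$n_solvent) / (25 * 4)
  expect_equal(sum(pr$rho_solvent) * 25 * attr(pr, "bin_width"),
               mean(rig$samples$n_solvent), tolerance = 1e-9)
  expect_lt(max(abs(pr$rho_solvent - expected)) / expected, 0.2)
})

test_that("brush height estimators follow their definitions", {
  # step profile uniform on [0, z1]: q98 -> 0.98 z1, moment -> z1
  z1 <- 4; bw <- 0.01
  z <- seq(bw / 2, 8, by = bw)
  rho <- ifelse(z < z1, 2, 0)
  prof <- fake_density_profile(z, rho, 0 * z, area = 49, h = 8,
                               bin_width = bw)
  est <- brush_height(prof)
  expect_equal(est$L_q, 0.98 * z1, tolerance = 1e-6)
  expect_equal(est$L_moment, z1, tolerance = 1e-6)

  # delta distribution at z0: quantile lands in that bin; moment is 2 z0
  z0 <- 2.505
  rho_d <- ifelse(abs(z - z0) < bw / 2, 100, 0)
  prof_d <- fake_density_profile(z, rho_d, 0 * z, 49, 8, bw)
  est_d <- brush_height(prof_d)
  expect_lt(abs(est_d$L_q - z0), bw)
  expect_equal(est_d$L_moment, 2 * z0, tolerance = 1e-6)

  expect_error(brush_height(fake_density_profile(z, 0 * z, 0 * z, 49, 8, bw)),
               "empty")
})

test_that("solvent penetration integrates the window", {
  bw <- 0.25
  z <- seq(bw / 2, 10, by = bw)
  prof <- fake_density_profile(z, 0 * z, rep(3, length(z)), area = 49,
                               h = 10, bin_width = bw)
  expect_equal(solvent_penetration(prof, c(2, 5)), 3 * 3 * 49)
  # partial-bin overlap
  expect_equal(solvent_penetration(prof, c(2.1, 2.2)), 3 * 0.1 * 49,
               tolerance = 1e-12)
  prof0 <- fake_density_profile(z, 0 * z, 0 * z, 49, 10, bw)
  expect_equal(solvent_penetration(prof0, c(2, 5)), 0)
  expect_error(solvent_penetration(prof, c(5, 2)), "empty")
  expect_error(solvent_penetration(prof, c(8, 12)), "within")
})

test_that("graft traces track liquid ends and freeze solid ones", {
  arch <- brush_architecture(data.frame(N = 4, Gamma = 0.3, kappa = 100),
                             mobility = "liquid")
  p <- simulation_parameters(architecture = arch, h = 6, seed = 8,
                             target_density = 0, gc_fraction = 0,
                             n_equilibration = 50, n_production = 500,
                             sample_interval = 10)
  run <- run_chain(build_system(p), p)
  tr <- graft_trace(run, chain_id = 1)
  expect_equal(nrow(tr), 50)
  msd <- attr(tr, "msd")
  expect_gt(msd$msd[nrow(msd)], 0)

  ps <- p
  ps$architecture$mobility <- "solid"
  runs <- run_chain(build_system(ps), ps)
  trs <- graft_trace(runs, chain_id = 1)
  expect_equal(length(unique(trs$x)), 1)
  expect_equal(max(attr(trs, "msd")$msd), 0)
  expect_error(graft_trace(run, chain_id = 999), "no such chain")
})

test_that("snapshot XYZ round-trips positions and labels", {
  sys <- random_chain_system(seed = 9, n_solvent = 10)
  f <- tempfile(fileext = ".xyz")
  write_xyz(sys, f, seed = 9, sweep = 0)
  back <- read_xyz(f)
  expect_equal(nrow(back$positions), nrow(sys$positions))
  expect_equal(back$h, sys$h)
  expect_equal(back$box, sys$box, tolerance = 1e-9)
  expect_equal(sum(back$species > 0), sys$n_brush)
  expect_equal(sort(back$positions[, 3]), sort(sys$positions[, 3]),
               tolerance = 1e-9)
})
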