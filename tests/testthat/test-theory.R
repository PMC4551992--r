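test_that("the compression law has its closed-form values and support", {
  pop <- brush_population(L = 10, s = 1)
  expect_equal(adg_pressure(20, pop), 0)   # balance exactly at contact
  expect_equal(adg_pressure(25, pop), 0)   # beyond contact
  expect_equal(adg_pressure(10, pop), 2^(9 / 4) - 2^(-3 / 4),
               tolerance = 1e-12)
  # positive on (0, 2L), one sign-change boundary at 2L
  h <- seq(0.5, 19.9, by = 0.1)
  expect_true(all(adg_pressure(h, pop) > 0))
  expect_error(adg_pressure(0, pop), "positive")
  expect_error(adg_pressure(-1, pop), "positive")
  # alternative contact convention switches the onset to L
  expect_equal(adg_pressure(12, pop, contact = "L"), 0)
  expect_gt(adg_pressure(8, pop, contact = "L"), 0)
})

test_that("quadrature, closed form, and brute force agree on the sphere force", {
  pop <- brush_population(L = 10, s = 1.3, amplitude = 1.7)
  h <- c(1, 2.5, 5, 9, 14, 19, 19.9)
  closed <- adg_sphere_force(h, pop)
  quad <- adg_sphere_force(h, pop, method = "quadrature")
  expect_equal(quad, closed, tolerance = 1e-8)

  # independent brute-force trapezoid at one million points
  u <- seq(5, 20, length.out = 1e6)
  brute <- 2 * pi * sum(diff(u) * (head(adg_pressure(u, pop), -1) +
                                     tail(adg_pressure(u, pop), -1)) / 2)
  expect_equal(adg_sphere_force(5, pop), brute, tolerance = 1e-6)

  expect_equal(adg_sphere_force(20, pop), 0)
  expect_equal(adg_sphere_force(31, pop), 0)
  # monotonically decreasing in h
  hs <- seq(1, 20, by = 0.25)
  expect_true(all(diff(adg_sphere_force(hs, pop)) <= 0))
})

test_that("multi-population forces are sums with per-population onsets", {
  p1 <- brush_population(L = 3, s = 1)
  p2 <- brush_population(L = 18, s = 1.2)
  p3 <- brush_population(L = 25, s = 2)
  h <- seq(0.5, 60, by = 0.5)
  expect_equal(multi_brush_force(h, list(p2)), adg_sphere_force(h, p2))
  expect_equal(multi_brush_force(h, list(p2, p2)),
               2 * adg_sphere_force(h, p2))
  f <- multi_brush_force(h, list(p1, p2, p3))
  for (L in c(3, 18, 25)) {
    expect_gt(multi_brush_force(2 * L - 1e-6, list(p1, p2, p3)), 0)
  }
  expect_equal(multi_brush_force(51, list(p1, p2, p3)), 0)
  expect_gt(multi_brush_force(49.9, list(p1, p2, p3)), 0)
  expect_error(multi_brush_force(h, list()), "at least one")
})

test_that("noiseless single-brush curves are recovered within 1%", {
  L_true <- 20; s_true <- 1.13
  spec <- synthetic_curve_spec(
    data.frame(L = L_true, Gamma = s_true^-2),
    h_grid = seq(2.2, 17.8, length.out = 40), noise_sd = 0, seed = 1)
  curve <- synth_force_curve(spec)
  fit <- fit_force_profile(curve, n_populations = 1, Gamma = s_true^-2,
                           free_amplitude = FALSE)
  expect_lt(abs(fit$L - L_true) / L_true, 0.01)

  # with a freed amplitude the length is still identified
  fit2 <- fit_force_profile(curve, n_populations = 1)
  expect_lt(abs(fit2$L - L_true) / L_true, 0.01)

  expect_error(
    fit_force_profile(data.frame(h = 1:20, F_over_R = rep(0, 20)), 1),
    "no usable points")
})

test_that("model comparison prefers three brushes for three-brush data", {
  pops <- data.frame(L = c(3, 18, 25), Gamma = c(1, 0.4, 0.15))
  spec <- synthetic_curve_spec(pops, h_grid = seq(0.5, 49, length.out = 80),
                               noise_sd = 0, seed = 2)
  curve <- synth_force_curve(spec)
  f3 <- fit_force_profile(curve, n_populations = 3, Gamma = pops$Gamma)
  f1 <- fit_force_profile(curve, n_populations = 1)
  expect_lt(f3$rss, f1$rss)
  expect_lt(f3$aicc, f1$aicc)
  # lengths ordered descending (label-switching broken)
  expect_true(all(diff(f3$L) <= 0))
})

test_that("parameter recovery is robust to 5% noise (median over curves)", {
  L_true <- 15
  errs <- vapply(1:20, function(s) {
    spec <- synthetic_curve_spec(
      data.frame(L = L_true, Gamma = 0.8),
      h_grid = seq(1.6, 13.4, length.out = 30), noise_sd = 0.05, seed = s)
    fit <- fit_force_profile(synth_force_curve(spec), 1, Gamma = 0.8,
                             free_amplitude = FALSE, n_starts = 3)
    abs(fit$L - L_true) / L_true
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("fitting tracks axis rescaling consistently", {
  spec <- synthetic_curve_spec(
    data.frame(L = 12, Gamma = 0.5),
    h_grid = seq(1.3, 10.7, length.out = 30), noise_sd = 0, seed = 3)
  curve <- synth_force_curve(spec)
  fit <- fit_force_profile(curve, 1)
  # h-axis scaling by c scales the fitted length by c
  c2 <- curve; c2$h <- 2 * c2$h
  fit2 <- fit_force_profile(c2, 1)
  expect_equal(fit2$L, 2 * fit$L, tolerance = 1e-3)
  # force-axis scaling with a free amplitude leaves the length unchanged
  c3 <- curve; c3$F_over_R <- 5 * c3$F_over_R
  fit3 <- fit_force_profile(c3, 1)
  expect_equal(fit3$L, fit$L, tolerance = 1e-3)
})

test_that("soft brushes out-push stiff ones whenever both are compressed", {
  soft <- brush_population(L = 9, s = 1.4)
  stiff <- brush_population(L = 4, s = 1.4)
  h <- seq(0.5, 2 * stiff$L - 1e-9, by = 0.1)
  expect_true(all(adg_sphere_force(h, soft) > adg_sphere_force(h, stiff)))
})
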