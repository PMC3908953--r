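p <- vessel_params()

test_that("annulus geometry reproduces hand-evaluated identities", {
  # zero-wall limit: the midwall and the lumen coincide
  g0 <- derive_geometry(c(eps = 0, tone = 0, span = 0.2,
                          r_mslack = 100e-6, wcsa = 0))
  expect_equal(g0$r_m, 100e-6)
  expect_equal(g0$h, 0)
  expect_equal(g0$r_i, 100e-6)
  # full-circumference span: cell length equals the circumference
  g1 <- derive_geometry(c(eps = 0, tone = 0, span = 1,
                          r_mslack = 100e-6, wcsa = 0))
  expect_equal(g1$l, 2 * pi * 100e-6)
  # hand-evaluated annulus: eps 0.5 on 80 um slack with wCSA 1.508e-8 m^2
  g2 <- derive_geometry(vessel_state(0.5, 0, 0.2, 80e-6, 1.508e-8))
  expect_equal(g2$r_m, 120e-6)
  expect_equal(g2$h, 1.508e-8 / (2 * pi * 120e-6))
  expect_equal(g2$h, 20e-6, tolerance = 1e-4)
  expect_equal(g2$r_i, g2$r_m - g2$h / 2)
  # degenerate: wall thicker than the lumen permits
  expect_error(derive_geometry(c(eps = -0.4, tone = 0, span = 0.2,
                                 r_mslack = 40e-6, wcsa = 1.5e-8)),
               class = "vesseladapt_degenerate_geometry")
})

test_that("geometry round-trips wcsa through (r_m, h) at 1e-12 relative", {
  set.seed(11)
  for (i in 1:50) {
    s <- c(eps = runif(1, -0.3, 1), tone = 0, span = runif(1, 0.05, 1),
           r_mslack = runif(1, 30e-6, 150e-6), wcsa = runif(1, 1e-9, 2e-8))
    g <- derive_geometry(s)
    expect_lt(abs(2 * pi * g$r_m * g$h - s[["wcsa"]]) / s[["wcsa"]], 1e-12)
  }
})

test_that("matrix stress is zero when slack, then increasing and convex", {
  expect_identical(matrix_stress(0, p), 0)
  expect_identical(matrix_stress(-0.3, p), 0)
  # frozen regression pin from hand evaluation of the bi-exponential law
  expect_equal(matrix_stress(0.6, p), 113647.943284, tolerance = 1e-10)
  eps <- seq(0.01, 1.2, by = 0.01)
  s <- matrix_stress(eps, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(diff(s)) > 0))
})

test_that("active capacity peaks at the optimal length, symmetric bell", {
  expect_equal(active_stress_capacity(p$l_opt, p), 250000)
  d <- 20e-6
  expect_equal(active_stress_capacity(p$l_opt + d, p),
               active_stress_capacity(p$l_opt - d, p))
  expect_lt(active_stress_capacity(p$l_opt + 3 * p$l_w, p), 0.001 * 250000)
  # frozen regression pin at the reference SMC length
  expect_equal(active_stress_capacity(80e-6, p), 180491.642569,
               tolerance = 1e-10)
  l <- seq(20e-6, 200e-6, by = 1e-6)
  cap <- active_stress_capacity(l, p)
  expect_equal(l[which.max(cap)], p$l_opt, tolerance = 1e-2)
})

test_that("cytoskeletal brake anchored at c_c3, negligible at l_ref, increasing", {
  expect_equal(cytoskeletal_stress(p$c_c3, p), 250000)
  at_ref <- cytoskeletal_stress(p$l_ref, p)
  expect_lt(at_ref, 0.01 * p$c_c1)
  # frozen regression pin
  expect_equal(at_ref, 13.6106273346, tolerance = 1e-10)
  l <- seq(40e-6, 160e-6, by = 1e-6)
  expect_true(all(diff(cytoskeletal_stress(l, p)) > 0))
})

test_that("mean wall stress composes the parallel elements", {
  # relaxed, slack, short cells: essentially stress-free wall
  s <- c(eps = 0, tone = 0, span = 0.05, r_mslack = 60e-6, wcsa = 1e-9)
  expect_lt(mean_wall_stress(s, p), 50)
  # full activation at zero strain: af-weighted capacity plus brake
  s1 <- vessel_state(0, 1, 0.16, 80e-6, 1.2e-8)
  g <- derive_geometry(s1)
  expect_equal(mean_wall_stress(s1, p),
               (active_stress_capacity(g$l, p) +
                  cytoskeletal_stress(g$l, p)) / 3)
  # composition closure: sigma within the span of the element stresses
  set.seed(7)
  for (i in 1:40) {
    s <- c(eps = runif(1, -0.2, 0.8), tone = runif(1), span = runif(1, 0.1, 0.5),
           r_mslack = runif(1, 40e-6, 120e-6), wcsa = runif(1, 2e-9, 2e-8))
    w <- wall_stresses(s, p)
    el <- c(w$sigma_p, w$sigma_a, w$sigma_c)
    expect_gte(w$sigma, min(el) - 1e-9)
    expect_lte(w$sigma, max(el) + 1e-9)
  }
})

test_that("Laplace and Poiseuille laws match direct evaluation exactly", {
  g <- list(r_i = 100e-6, h = 20e-6)
  expect_identical(laplace_stress(0, g), 0)
  expect_equal(laplace_stress(mmHg(100), g), 66661)
  g2 <- list(r_i = 100e-6, h = 40e-6)
  expect_equal(laplace_stress(mmHg(100), g2), laplace_stress(mmHg(100), g) / 2)
  expect_error(laplace_stress(1000, list(r_i = 1e-4, h = 0)), "zero")

  expect_identical(wall_shear_stress(0, 50e-6, p), 0)
  expect_equal(wall_shear_stress(0.25e-9, 100e-6, p), 1.11408460164,
               tolerance = 1e-10)
  expect_equal(wall_shear_stress(0.25e-9, 200e-6, p),
               wall_shear_stress(0.25e-9, 100e-6, p) / 8)
  expect_error(wall_shear_stress(1e-9, -1e-6, p),
               class = "vesseladapt_degenerate_geometry")
})
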