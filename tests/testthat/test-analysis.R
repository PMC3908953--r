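p <- vessel_params()
base <- vessel_steady_state(params = p)

test_that("pressure-radius curves pass through the working point and order correctly", {
  grid <- mmHg(seq(20, 140, by = 5))
  cf <- pressure_radius_curve(grid, "frozen", base, p)
  cp <- pressure_radius_curve(grid, "passive", base, p)
  ca <- pressure_radius_curve(grid, "active", base, p)
  # the working point lies on the frozen curve
  i80 <- which.min(abs(cf$P - mmHg(80)))
  expect_equal(cf$r_i[i80], base$derived[["r_i"]], tolerance = 1e-9)
  # passive distension is monotone in pressure
  expect_true(all(diff(cp$r_i) > 0))
  # active <= frozen <= passive everywhere
  expect_true(all(ca$r_i <= cf$r_i + 1e-12))
  expect_true(all(cf$r_i <= cp$r_i + 1e-12))
})

test_that("radius reserve is >= 1 and equals 1 for a fully dilated state", {
  expect_gte(base$derived[["radius_reserve"]], 1)
  # a structure relaxed to tone 0 at mechanical equilibrium has no reserve
  eps0 <- mechanical_equilibrium(base$state[["span"]],
                                 base$state[["r_mslack"]],
                                 base$state[["wcsa"]], 0,
                                 base$inputs[["P"]], p)
  relaxed <- base
  relaxed$state[["eps"]] <- eps0
  relaxed$state[["tone"]] <- 0
  relaxed$geometry <- derive_geometry(relaxed$state)
  expect_equal(radius_reserve(relaxed), 1, tolerance = 1e-9)
})

test_that("tension match scales as the span identity implies", {
  # halving the span doubles the optimal midwall radius
  s2 <- base
  s2$state[["span"]] <- base$state[["span"]] / 2
  pfun <- function(ss) p$l_opt / (2 * pi * ss$state[["span"]])
  expect_equal(pfun(s2), 2 * pfun(base))
  # tension match is invariant under pure rescaling of flow
  tm <- vapply(c(0.125, 0.25, 0.5), function(q)
    vessel_steady_state(Q = uL_per_s(q), params = p)$derived[["tension_match"]],
    numeric(1))
  expect_lt(diff(range(tm)) / mean(tm), 1e-6)
})

test_that("step responses reproduce the adaptation cascade", {
  # full model, pressure step: radius and tone fully restored, wall grown
  sr <- step_response("GROWTH", P = mmHg(100), t_end = 1e8, params = p)
  expect_equal(attr(sr, "verdict"), "stable")
  n <- nrow(sr)
  expect_equal(sr$r_i[n], sr$r_i[1], tolerance = 1e-3)
  expect_equal(sr$tone[n], sr$tone[1], tolerance = 1e-3)
  expect_gt(sr$wcsa[n], 1.2 * sr$wcsa[1])
  # tone responds much earlier than structure (log-time separation)
  t_tone <- sr$time[min(which(abs(sr$tone - sr$tone[1]) > 0.02))]
  t_struct <- sr$time[min(which(abs(sr$wcsa / sr$wcsa[1] - 1) > 0.02))]
  expect_lt(t_tone * 50, t_struct)
  # eutrophic-only model, flow step: outward remodeling, thin wall, high tone
  sq <- step_response("REMOD", Q = uL_per_s(0.5), t_end = 1e8, params = p)
  m <- nrow(sq)
  expect_gt(sq$r_islack[m], sq$r_islack[1])
  expect_lt(sq$h[m], sq$h[1])
  expect_gt(sq$tone[m], sq$tone[1])
})

test_that("steady-state map shows homeostasis in the full model and absorbs instability", {
  m <- steady_state_map(variants = c("GROWTH", "FUNCTKO"),
                        P_grid = mmHg(c(60, 100, 140)),
                        Q_grid = uL_per_s(c(0.125, 0.5)),
                        CON_grid = c(0, 15000),
                        DIL_grid = c(0, 1.5), params = p)
  g <- m[m$variant == "GROWTH", ]
  expect_true(all(g$verdict == "stable"))
  # radius is pressure-insensitive at steady state
  expect_lt(max(abs(g$r_i_rel[g$input == "P"] - 1)), 1e-6)
  # shear rises under constrictors, falls under dilators
  expect_gt(g$tau_rel[g$input == "CON" & g$value == 15000], 1)
  expect_lt(g$tau_rel[g$input == "DIL" & g$value == 1.5], 1)
  # no tone regulation: every block unstable
  ko <- m[m$variant == "FUNCTKO", ]
  expect_true(all(ko$verdict %in% c("collapse", "runaway")))
})

test_that("sensitivity matrix reproduces the structural identities and zeros", {
  S <- sensitivity_matrix(params = p)
  expect_equal(S["l", "l_ref"], 1, tolerance = 5e-3)
  expect_equal(S["sigma", "sigma_ref"], 1, tolerance = 5e-3)
  zero_cells <- rbind(
    c("tone", "ecf"), c("l", "ecf"), c("sigma", "ecf"),
    c("l", "beta_strain"), c("l", "sigma_ref"),
    c("sigma", "l_ref"), c("sigma", "beta_strain"),
    c("tension_match", "ecf"), c("radius_reserve", "ecf"))
  for (i in seq_len(nrow(zero_cells)))
    expect_lt(abs(S[zero_cells[i, 1], zero_cells[i, 2]]), 5e-3)
  # sign pattern of every remaining entry
  signs <- matrix(c(
    +1, -1, +1, -1,
    0, -1, +1, +1,
    0, +1,  0,  0,
    +1, -1, +1, -1,
    +1, -1, +1, -1,
    0,  0,  0, +1,
    -1, +1, -1, +1,
    0, -1, -1, +1,
    0, +1, +1, -1), 9, 4, byrow = TRUE,
    dimnames = dimnames(S))
  nz <- signs != 0
  expect_true(all(sign(S[nz]) == signs[nz]))
})

test_that("shear stress stays flow-independent under wide parameter variation", {
  flows <- uL_per_s(c(0.125, 0.25, 0.5))
  for (pn in c("ecf", "l_ref", "beta_strain", "sigma_ref")) {
    for (f in c(0.5, 1.5)) {
      ov <- list(); ov[[pn]] <- unclass(p)[[pn]] * f
      pv <- do.call(vessel_params, ov)
      taus <- vapply(flows, function(q) {
        ss <- vessel_steady_state(Q = q, params = pv, derived = FALSE)
        if (ss$verdict == "stable") ss$derived[["tau"]] else NA_real_
      }, numeric(1))
      taus <- taus[is.finite(taus)]
      if (length(taus) > 1)
        expect_lt(diff(range(taus)) / mean(taus), 1e-6)
    }
  }
})

test_that("dilator scan conserves the total dilatory stimulus and finds the runaway regime", {
  sc <- dilator_scan(seq(0, 5, by = 0.5), params = p)
  st <- sc[sc$verdict == "stable", ]
  expect_equal(st$sum_dyn_cm2[st$DIL == 0], st$tau_dyn_cm2[st$DIL == 0])
  expect_lt(diff(range(st$sum_dyn_cm2)) / mean(st$sum_dyn_cm2), 1e-6)
  expect_true(any(sc$verdict == "runaway"))
  # shear falls one-for-one as the dilator rises
  expect_true(all(diff(st$tau_dyn_cm2) < 0))
})
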