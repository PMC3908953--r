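p <- vessel_params()

test_that("tone-reducing factor follows the dilation Hill curve", {
  expect_equal(tone_reducing_factor(0, 0, p), 1)
  expect_equal(tone_reducing_factor(p$tau_50, 0, p), 0.5)
  expect_equal(tone_reducing_factor(2, 3, p), 0.5)  # stimuli add
  # endothelial dysfunction abolishes dilation entirely
  p0 <- vessel_params(ecf = 0)
  expect_equal(tone_reducing_factor(100, 50, p0), 1)
  tau <- seq(0, 30, by = 0.5)
  trf <- tone_reducing_factor(tau, 0, p)
  expect_true(all(diff(trf) < 0))
  expect_true(all(trf >= 1 - p$ecf & trf <= 1))
})

test_that("equilibrium tone is the product of activation and TRF", {
  expect_equal(equilibrium_tone(0, 0, 1, p), 0)
  expect_equal(equilibrium_tone(p$sigma_50, 0, 1, p), 0.5)
  expect_equal(equilibrium_tone(20000, 10000, 1, p), 0.5)  # CON adds
  # both Hill curves at half-max: tone 0.25
  trf <- tone_reducing_factor(5, 0, p)
  expect_equal(equilibrium_tone(30000, 0, trf, p), 0.25)
  sig <- seq(0, 2e5, by = 1e3)
  a <- equilibrium_tone(sig, 0, 1, p)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("variant masks encode the model hierarchy and knockouts", {
  expect_equal(sum(vessel_variant("MECH")), 1)
  expect_true(vessel_variant("MECH")[["mech"]])
  expect_equal(as.logical(vessel_variant("FUNCT")),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(vessel_variant("GROWTH")))
  # every variant keeps mechanics on; knockouts drop exactly one process
  for (v in c("MECH", "FUNCT", "PLAST", "REMOD", "GROWTH",
              "FUNCTKO", "PLASTKO", "REMODKO"))
    expect_true(vessel_variant(v)[["mech"]])
  kos <- c(FUNCTKO = "tone", PLASTKO = "plasticity", REMODKO = "remodeling")
  for (nm in names(kos)) {
    m <- vessel_variant(nm)
    expect_equal(names(m)[!m], unname(kos[nm]))
  }
  expect_error(vessel_variant("NOPE"), "unknown model variant")
})

test_that("state derivative matches a direct symbolic evaluation on random states", {
  set.seed(42)
  inputs0 <- c(P = mmHg(80), Q = uL_per_s(0.25), CON = 0, DIL = 0)
  for (i in 1:100) {
    s <- c(eps = runif(1, -0.2, 0.8), tone = runif(1),
           span = runif(1, 0.08, 0.5), r_mslack = runif(1, 40e-6, 120e-6),
           wcsa = runif(1, 2e-9, 1.5e-8))
    inputs <- inputs0 * c(runif(1, 0.5, 2), runif(1, 0.5, 2), 1, 1)
    inputs[3:4] <- c(runif(1, 0, 2e4), runif(1, 0, 3))
    d <- state_derivative(0, s, inputs, p, vessel_variant("GROWTH"))
    # independent evaluation, written out term by term
    r_m <- s[["r_mslack"]] * (1 + s[["eps"]])
    h <- s[["wcsa"]] / (2 * pi * r_m)
    r_i <- r_m - h / 2
    l <- s[["span"]] * 2 * pi * r_m
    sig <- (oracle_sigma_p(s[["eps"]], p) +
              s[["tone"]] * oracle_sigma_acap(l, p) +
              oracle_sigma_c(l, p)) / 3
    tau <- 4 * p$eta * inputs[["Q"]] / (pi * r_i^3)
    a_eq <- oracle_hill(sig + inputs[["CON"]], p$sigma_50, p$hc) *
      (1 - oracle_hill(tau + inputs[["DIL"]], p$tau_50, p$hd))
    expected <- c(
      eps = p$k_mech * (inputs[["P"]] * r_i / h - sig),
      tone = p$k_tone * (a_eq - s[["tone"]]),
      span = p$k_span * s[["span"]] * (l / p$l_ref) * (p$l_ref - l),
      r_mslack = p$k_slack * s[["r_mslack"]] *
        (p$beta_strain * s[["eps"]] - p$alpha_tone * s[["tone"]]),
      wcsa = p$k_growth * s[["wcsa"]] * (sig - p$sigma_ref))
    expect_equal(d, expected, tolerance = 1e-14)
  }
})

test_that("masked processes contribute exactly zero rate", {
  s <- c(eps = 0.3, tone = 0.4, span = 0.2, r_mslack = 70e-6, wcsa = 1.2e-8)
  inputs <- c(P = mmHg(100), Q = uL_per_s(0.5), CON = 0, DIL = 0)
  d_full <- state_derivative(0, s, inputs, p, vessel_variant("GROWTH"))
  d_mech <- state_derivative(0, s, inputs, p, vessel_variant("MECH"))
  expect_identical(as.numeric(d_mech[2:5]), rep(0, 4))
  expect_equal(d_mech[["eps"]], d_full[["eps"]])
  d_ko <- state_derivative(0, s, inputs, p, vessel_variant("PLASTKO"))
  expect_identical(d_ko[["span"]], 0)
  expect_equal(d_ko[c("eps", "tone", "r_mslack", "wcsa")],
               d_full[c("eps", "tone", "r_mslack", "wcsa")])
})

test_that("rate signs follow the adaptation biology", {
  inputs <- c(P = mmHg(80), Q = uL_per_s(0.25), CON = 0, DIL = 0)
  # strained, fully relaxed wall remodels outward
  s <- c(eps = 0.4, tone = 0, span = 0.159, r_mslack = 65e-6, wcsa = 1.2e-8)
  d <- state_derivative(0, s, inputs, p, vessel_variant("GROWTH"))
  expect_gt(d[["r_mslack"]], 0)
  # deep tone without strain remodels inward
  s2 <- s; s2[["eps"]] <- 0; s2[["tone"]] <- 0.9
  expect_lt(state_derivative(0, s2, inputs, p)[["r_mslack"]], 0)
  # wall stress above the growth reference grows the wall
  s3 <- c(eps = 0.9, tone = 1, span = 0.2, r_mslack = 65e-6, wcsa = 1.2e-8)
  expect_gt(state_derivative(0, s3, inputs, p)[["wcsa"]], 0)
  # short cells increase their span, long cells reduce it
  s4 <- s; s4[["span"]] <- 0.05
  expect_gt(state_derivative(0, s4, inputs, p)[["span"]], 0)
  s5 <- s; s5[["span"]] <- 0.5
  expect_lt(state_derivative(0, s5, inputs, p)[["span"]], 0)
})

test_that("characteristic time scales order as mechanics < tone << plasticity <= remodeling <= growth", {
  # characteristic relaxation rates (1/s) near the working point: the rate
  # constant times the magnitude of its driving term's state sensitivity
  ss <- vessel_steady_state(derived = FALSE)
  g <- derive_geometry(ss$state)
  # stress/strain slope at the working point (numerical, matrix branch)
  slope <- (matrix_stress(ss$state[["eps"]] + 1e-5, p) -
              matrix_stress(ss$state[["eps"]] - 1e-5, p)) / 2e-5
  r_mech <- p$k_mech * slope
  r_tone <- p$k_tone
  r_span <- p$k_span * g$l
  r_slack <- p$k_slack
  r_growth <- p$k_growth * p$sigma_ref
  expect_gt(r_mech, r_tone)
  expect_gt(r_tone, 10 * r_span)
  expect_gte(r_span, r_slack)
  expect_gte(r_slack, r_growth)
})

test_that("protocols validate segments and convert clinical units", {
  pr <- stimulus_protocol(P = c(80, 100), Q = 0.25, t_start = c(0, 1000),
                          units = "clinical")
  expect_equal(pr$P, mmHg(c(80, 100)))
  expect_equal(pr$Q, rep(uL_per_s(0.25), 2))
  expect_equal(protocol_inputs(pr, 999)[["P"]], mmHg(80))
  expect_equal(protocol_inputs(pr, 1000)[["P"]], mmHg(100))
  expect_error(stimulus_protocol(t_start = c(5, 10)), "start at t = 0")
  expect_error(stimulus_protocol(P = c(80, 90), t_start = c(0, 0)),
               "strictly increasing")
  expect_error(stimulus_protocol(DIL = -1), "allow_negative")
  expect_silent(stimulus_protocol(DIL = -1, allow_negative = TRUE))
})
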