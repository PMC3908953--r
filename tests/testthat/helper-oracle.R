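# Independent fixed-point oracle: the full-model steady state solved by
# direct algebra (scalar root for tone, closed forms for the geometry),
# written from the constitutive formulas themselves. Entirely separate from
# the package's integrate-then-polish path.

oracle_sigma_p <- function(eps, p) {
  ifelse(eps <= 0, 0,
         p$c_p1 * (exp(p$c_p3 * eps) - 1) + p$c_p2 * (exp(p$c_p4 * eps) - 1))
}
oracle_sigma_acap <- function(l, p) p$sigma_amax * exp(-((l - p$l_opt) / p$l_w)^2)
oracle_sigma_c <- function(l, p) p$c_c1 * exp(p$c_c2 * (l - p$c_c3) / p$c_c3)
oracle_hill <- function(x, K, n) ifelse(x <= 0, 0, x^n / (x^n + K^n))

# analytic GROWTH fixed point; NULL when no steady state exists (runaway)
oracle_growth_fp <- function(p, P = mmHg(80), Q = uL_per_s(0.25),
                             CON = 0, DIL = 0) {
  bal <- function(A) {
    eps <- p$alpha_tone * A / p$beta_strain
    p$af_p * oracle_sigma_p(eps, p) +
      p$af_a * A * oracle_sigma_acap(p$l_ref, p) +
      p$af_c * oracle_sigma_c(p$l_ref, p) - p$sigma_ref
  }
  A <- uniroot(bal, c(1e-9, 1), tol = 1e-15)$root
  trf <- A / oracle_hill(p$sigma_ref + CON, p$sigma_50, p$hc)
  Hd <- (1 - trf) / p$ecf
  if (Hd <= 0 || Hd >= 1) return(NULL)
  x <- p$tau_50 * (Hd / (1 - Hd))^(1 / p$hd)
  tau <- x - DIL
  if (tau <= 0) return(NULL)
  r_i <- (4 * p$eta * Q / (pi * tau))^(1 / 3)
  h <- P * r_i / p$sigma_ref
  r_m <- r_i + h / 2
  eps <- p$alpha_tone * A / p$beta_strain
  list(eps = eps, tone = A, span = p$l_ref / (2 * pi * r_m),
       r_mslack = r_m / (1 + eps), wcsa = 2 * pi * r_m * h,
       r_i = r_i, h = h, tau = tau)
}

# REMOD fixed point (wcsa frozen at `wcsa0`): 2-D algebraic root in
# (tone, r_m), solved by nested scalar root-finding
oracle_remod_fp <- function(p, wcsa0, P = mmHg(80), Q = uL_per_s(0.25),
                            CON = 0, DIL = 0, tone_hint = 0.4) {
  sigma_of <- function(A) {
    eps <- p$alpha_tone * A / p$beta_strain
    p$af_p * oracle_sigma_p(eps, p) +
      p$af_a * A * oracle_sigma_acap(p$l_ref, p) +
      p$af_c * oracle_sigma_c(p$l_ref, p)
  }
  # given tone, Laplace fixes r_m through sigma = P * r_i / h
  rm_of <- function(A) {
    sig <- sigma_of(A)
    f <- function(r_m) {
      h <- wcsa0 / (2 * pi * r_m)
      sig - P * (r_m - h / 2) / h
    }
    uniroot(f, c(sqrt(wcsa0 / (4 * pi)) * (1 + 1e-9), 1e-2),
            tol = 1e-16)$root
  }
  # tone equilibrium closes the system
  g <- function(A) {
    r_m <- rm_of(A)
    h <- wcsa0 / (2 * pi * r_m)
    tau <- 4 * p$eta * Q / (pi * (r_m - h / 2)^3)
    trf <- 1 - p$ecf * oracle_hill(tau + DIL, p$tau_50, p$hd)
    oracle_hill(sigma_of(A) + CON, p$sigma_50, p$hc) * trf - A
  }
  # the tone equation can have several interior roots (stable and unstable
  # branches); locate them all by grid bracketing and keep the one nearest
  # the hint
  grid <- seq(0.005, 0.995, by = 0.005)
  gv <- vapply(grid, g, numeric(1))
  idx <- which(gv[-1] * gv[-length(gv)] <= 0)
  if (!length(idx)) stop("oracle_remod_fp: no root bracketed")
  roots <- vapply(idx, function(i)
    uniroot(g, grid[c(i, i + 1)], tol = 1e-15)$root, numeric(1))
  A <- roots[which.min(abs(roots - tone_hint))]
  r_m <- rm_of(A)
  h <- wcsa0 / (2 * pi * r_m)
  eps <- p$alpha_tone * A / p$beta_strain
  list(eps = eps, tone = A, span = p$l_ref / (2 * pi * r_m),
       r_mslack = r_m / (1 + eps), wcsa = wcsa0, r_i = r_m - h / 2, h = h)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
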