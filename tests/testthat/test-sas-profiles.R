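test_that("generalized Gaussian coil normalizes, reduces to Debye, and is monotone", {
  for (nu in c(0.45, 0.5, 0.53, 0.6)) {
    expect_equal(gauss_coil_formfactor(0, rg = 40, nu = nu), 1)
    q <- exp(seq(log(0.01 / 40), log(10 / 40), length.out = 80))
    P <- gauss_coil_formfactor(q, 40, nu)
    expect_true(all(diff(P) < 0))          # monotone decreasing
  }
  # nu = 1/2: exact Debye equivalence over q*RG in [0.01, 10]
  rg <- 45
  q <- exp(seq(log(0.01 / rg), log(10 / rg), length.out = 200))
  expect_lt(max(abs(gauss_coil_formfactor(q, rg, 0.5) / debye_fn(q, rg) - 1)),
            1e-6)
  expect_error(gauss_coil_formfactor(0.1, 40, nu = 1.2), "nu")
  expect_error(gauss_coil_formfactor(0.1, 40, nu = 0), "nu")
})

test_that("gauss-coil fit recovers parameters, noise-free and under noise", {
  q <- saxs_grid()
  exact <- scattering_curve(q, gauss_coil_formfactor(q, 45, 0.53),
                            sigma = 0.01 * gauss_coil_formfactor(q, 45, 0.53))
  f <- fit_gauss_coil(exact, fit_background = FALSE)
  expect_lt(abs(f$rg / 45 - 1), 1e-4)
  expect_lt(abs(f$nu / 0.53 - 1), 1e-4)

  noisy <- make_saxs(45, 0.53, noise_frac = 0.02, seed = 101)
  fn <- fit_gauss_coil(noisy)
  expect_lt(abs(fn$rg - 45), 3 * fn$se["rg"])
  expect_lt(abs(fn$nu - 0.53), 3 * fn$se["nu"])
})

test_that("fitted nu distinguishes 0.48 from 0.53 at 2% noise", {
  f48 <- fit_gauss_coil(make_saxs(42, 0.48, noise_frac = 0.02, seed = 7))
  f53 <- fit_gauss_coil(make_saxs(42, 0.53, noise_frac = 0.02, seed = 8))
  # non-overlapping 2-sigma intervals
  expect_lt(f48$nu + 2 * f48$se["nu"], f53$nu - 2 * f53$se["nu"])
})

test_that("Guinier analysis is exact on pure Gaussians and honest on coils", {
  q <- exp(seq(log(0.004), log(0.5), length.out = 200))
  # pure exp(-R^2 q^2 / 3): machine-precision recovery
  I <- exp(-30^2 * q^2 / 3)
  g <- guinier_fit(scattering_curve(q, I, sigma = 0.01 * I), 1.1)
  expect_equal(g$rguinier, 30, tolerance = 1e-10)
  expect_lte(g$qmaxR, 1.1 * (1 + 1e-9))

  # exact Gaussian-coil curve: small systematic underestimate, < 5%
  Ic <- gauss_coil_formfactor(q, 30, 0.5)
  gc <- guinier_fit(scattering_curve(q, Ic, sigma = 0.01 * Ic), 1.1)
  expect_lt(abs(gc$rguinier - 30) / 30, 0.05)

  # flat curve: no measurable radius, flagged
  gf <- guinier_fit(scattering_curve(q, rep(2, 200), sigma = rep(0.02, 200)))
  expect_equal(gf$rguinier, 0)
  expect_equal(gf$flag, "below-resolution")
})

test_that("Guinier radius approaches R_G as the qmaxR limit shrinks", {
  q <- exp(seq(log(0.002), log(0.5), length.out = 250))
  I <- gauss_coil_formfactor(q, 30, 0.5)
  cv <- scattering_curve(q, I, sigma = 0.01 * I)
  r <- vapply(c(1.3, 0.9, 0.5), function(lim) guinier_fit(cv, lim)$rguinier, 0)
  expect_true(all(diff(r) > 0))            # monotone approach from below
  expect_true(all(r < 30))
  expect_lt(abs(r[3] - 30) / 30, 0.01)
})

test_that("Kratky transform is the elementwise q^2 scaling", {
  cv <- scattering_curve(c(0.01, 0.1, 0.3), c(1, 0.5, 0.1), c(0.01, 0.01, 0.01))
  k <- kratky_transform(cv)
  expect_equal(k$qsqI, cv$q^2 * cv$I)
  expect_equal(k$sigma, cv$q^2 * cv$sigma)
  expect_equal(k$q, cv$q)
})

test_that("structure-factor estimation divides out the form factor exactly", {
  q <- saxs_grid(80)
  I <- gauss_coil_formfactor(q, 35, 0.5)
  dil <- scattering_curve(q, I, sigma = 0.01 * I)
  # identical inputs: S = 1 everywhere
  s1 <- estimate_structure_factor(dil, dil)
  expect_equal(s1$S, rep(1, length(q)), tolerance = 1e-12)
  # concentrated = dilute x PY S(q): recovers S(q) to numerical precision
  Spy <- hard_sphere_sq(q, r_hs = 30, phi = 0.1)
  conc <- scattering_curve(q, I * Spy, sigma = 0.01 * I * Spy)
  s2 <- estimate_structure_factor(conc, dil)
  expect_equal(s2$S, Spy, tolerance = 1e-10)
})

test_that("structure-factor uncertainties follow quotient propagation", {
  set.seed(5)
  q <- saxs_grid(40)
  Ic <- gauss_coil_formfactor(q, 35, 0.5) * (1 + 0.02 * rnorm(40))
  Id <- gauss_coil_formfactor(q, 35, 0.5) * (1 + 0.02 * rnorm(40))
  sc <- 0.02 * Ic; sd_ <- 0.03 * Id
  conc <- scattering_curve(q, Ic, sc)
  dil <- scattering_curve(q, Id, sd_)
  s <- estimate_structure_factor(conc, dil, c_conc = 5, c_dil = 0.5)
  S_expect <- (Ic / 5) / (Id / 0.5)
  sig_expect <- abs(S_expect) * sqrt((sc / Ic)^2 + (sd_ / Id)^2)
  expect_equal(s$S, S_expect, tolerance = 1e-12)
  expect_equal(s$sigma, sig_expect, tolerance = 1e-12)
})

test_that("dilute points with non-positive intensity are masked with warning", {
  q <- saxs_grid(30)
  I <- gauss_coil_formfactor(q, 35, 0.5)
  Id <- I; Id[15] <- -1e-3
  dil <- scattering_curve(q, Id, sigma = 0.01 * I)
  conc <- scattering_curve(q, I, sigma = 0.01 * I)
  expect_warning(estimate_structure_factor(conc, dil), "masked")
})

test_that("Percus-Yevick structure factor satisfies its closed-form limits", {
  q <- seq(1e-6, 3, length.out = 400)
  expect_equal(hard_sphere_sq(q, 30, 0), rep(1, length(q)))
  for (phi in c(0.05, 0.2)) {
    S0 <- hard_sphere_sq(1e-9, 10, phi)
    expect_lt(abs(S0 - (1 - phi)^4 / (1 + 2 * phi)^2), 1e-8)
  }
  # q -> infinity asymptote: within 1e-3 for q R > 50
  expect_lt(max(abs(hard_sphere_sq(seq(5.5, 10, 0.1), 10, 0.2) - 1)), 1e-3)
  expect_error(hard_sphere_sq(q, 10, 0.8), "phi")
  expect_error(hard_sphere_sq(q, 10, -0.1), "phi")
})

test_that("PY series and direct branches agree at the splice", {
  for (phi in c(0.05, 0.3)) {
    qa <- 0.0499 / (2 * 10); qb <- 0.0501 / (2 * 10)
    expect_lt(abs(hard_sphere_sq(qa, 10, phi) - hard_sphere_sq(qb, 10, phi)),
              1e-5)
  }
})

test_that("hard-sphere fit recovers (R_hs, phi)", {
  q <- seq(0.005, 0.4, length.out = 120)
  Strue <- hard_sphere_sq(q, 28, 0.12)
  sq <- structure(list(q = q, S = Strue, sigma = rep(0.005, length(q))),
                  class = "structure_factor_curve")
  f <- fit_hard_sphere(sq)
  expect_lt(abs(f$r_hs / 28 - 1), 1e-6)
  expect_lt(abs(f$phi - 0.12), 1e-6)

  set.seed(9)
  noisy <- structure(list(q = q, S = Strue * (1 + 0.02 * rnorm(length(q))),
                          sigma = 0.02 * Strue),
                     class = "structure_factor_curve")
  fn <- fit_hard_sphere(noisy)
  expect_lt(abs(fn$r_hs - 28), 3 * fn$se["r_hs"])
  expect_lt(abs(fn$phi - 0.12), 3 * fn$se["phi"])

  flat <- structure(list(q = q, S = rep(1, length(q)),
                         sigma = rep(0.01, length(q))),
                    class = "structure_factor_curve")
  expect_lt(fit_hard_sphere(flat)$phi, 1e-4)
})

test_that("stiff-segment marker q* = 1.91 / lp", {
  expect_equal(stiff_segment_q(19.1), 0.1)
  expect_equal(stiff_segment_q(38.2), 0.05)
  expect_error(stiff_segment_q(0), "persistence")
})

test_that("scattering_curve validates its invariants", {
  expect_error(scattering_curve(c(0.2, 0.1), 1:2, c(1, 1)), "increasing")
  expect_error(scattering_curve(c(-0.1, 0.1), 1:2, c(1, 1)), "q must")
  expect_error(scattering_curve(c(0.1, 0.2), 1:2, c(1, 0)), "sigma")
  expect_error(scattering_curve(c(0.1, 0.2), 1:3, c(1, 1)), "length")
})
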