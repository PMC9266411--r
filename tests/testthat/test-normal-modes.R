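test_that("ANM has a six-fold null space with orthonormal nontrivial modes", {
  set.seed(3)
  ch <- bead_chain(fjc_coords(60))
  md <- anm_modes(ch)
  expect_equal(sum(md$all_values < 1e-8 * max(md$all_values)), 6)
  G <- crossprod(md$vectors)
  expect_equal(G, diag(md$n_modes), tolerance = 1e-10)
  expect_true(all(diff(md$values) >= -1e-12))  # ascending
  expect_error(anm_modes(ch, n_modes = 200), "too short")
})

test_that("ANM Hessian agrees with finite differences; softest mode is the bend", {
  # bent 3-bead toy chain; energy = sum over contacts of (|r_ij| - |r0_ij|)^2/2
  xyz0 <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8 + 3.8 * cos(2.6), 3.8 * sin(2.6), 0))
  ch <- bead_chain(xyz0)
  cutoff <- 15
  energy <- function(x) {
    p <- matrix(x, ncol = 3, byrow = FALSE)
    e <- 0
    for (i in 1:2) for (j in (i + 1):3) {
      r0 <- sqrt(sum((xyz0[j, ] - xyz0[i, ])^2))
      if (r0 <= cutoff) e <- e + (sqrt(sum((p[j, ] - p[i, ])^2)) - r0)^2 / 2
    }
    e
  }
  x0 <- as.numeric(xyz0)
  h <- 1e-5
  Hfd <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    ei <- ej <- rep(0, 9); ei[i] <- h; ej[j] <- h
    Hfd[i, j] <- (energy(x0 + ei + ej) - energy(x0 + ei) -
                  energy(x0 + ej) + energy(x0)) / h^2
  }
  # compare spectra (coordinate layouts differ: fd is column-major xyz)
  perm <- as.numeric(t(matrix(1:9, 3, 3)))   # map (x1..x3,y1..y3,z1..z3)->(x1,y1,z1,...)
  Hfd <- Hfd[perm, perm]
  md <- anm_modes(ch, cutoff = cutoff, n_modes = 3)
  ev_fd <- sort(eigen(Hfd, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(sum(abs(ev_fd) < 1e-4), 6)
  expect_equal(md$values, ev_fd[7:9], tolerance = 1e-4)

  # softest nontrivial mode is the bend: central bead moves opposite the ends
  m1 <- matrix(md$vectors[, 1], ncol = 3, byrow = TRUE)
  ends <- (m1[1, ] + m1[3, ]) / 2
  expect_lt(sum(ends * m1[2, ]), 0)
})

test_that("multipole expansion reproduces the Debye sum and its limits", {
  set.seed(4)
  ch <- bead_chain(fjc_coords(40))
  Q <- c(0.02, 0.08, 0.15, 0.25)
  mt <- multipole_sl(ch, Q)
  expect_lt(max(abs(colSums(mt$S) / debye_scattering(ch, Q) - 1)), 1e-6)
  # S_l >= 0 and S_l(Q -> 0) -> 0 for l >= 1
  expect_true(all(mt$S >= -1e-12))
  tiny <- multipole_sl(ch, 1e-6, lmax = 6)
  expect_lt(max(tiny$S[-1, ]), 1e-10)
  expect_equal(unname(tiny$S[1, ]), sum(ch$b)^2, tolerance = 1e-8)

  # single effective scatterer (b zero elsewhere): only l = 0 survives
  ch1 <- bead_chain(ch$coords, b = c(2, rep(0, 39)))
  m1 <- multipole_sl(ch1, Q, lmax = 8)
  expect_equal(unname(m1$S[1, ]), rep(4, 4), tolerance = 1e-10)  # S_0 = b^2
  expect_lt(max(m1$S[-1, ]), 1e-12)
})

test_that("lmax rule is converged", {
  set.seed(14)
  ch <- bead_chain(fjc_coords(50))
  Q <- c(0.1, 0.2)
  r <- sweep(ch$coords, 2, colMeans(ch$coords))
  lbase <- ceiling(max(Q) * max(sqrt(rowSums(r^2)))) + 10
  s1 <- colSums(multipole_sl(ch, Q, lmax = lbase)$S)
  s2 <- colSums(multipole_sl(ch, Q, lmax = lbase + 15)$S)
  expect_lt(max(abs(s1 / s2 - 1)), 1e-6)
})

test_that("mode amplitude A(q) obeys its algebraic contracts", {
  set.seed(5)
  ch <- bead_chain(fjc_coords(80))
  md <- anm_modes(ch)
  Q <- c(0.05, 0.1, 0.17)
  f0 <- mode_formfactor_amplitude(ch, md, a = 0, Q = Q)
  expect_equal(f0$A, rep(0, 3))
  f <- mode_formfactor_amplitude(ch, md, a = 10, Q = Q)
  expect_true(all(f$A >= 0 & f$A <= 1))
  # quadratic amplitude dependence of the mode term before the ratio
  fa <- mode_formfactor_amplitude(ch, md, a = 4, Q = Q)
  s_full <- 4^2 * colSums(fa$Falpha)
  s_half <- 2^2 * colSums(fa$Falpha)
  expect_equal(s_half / s_full, rep(0.25, 3))
  # orientational-average convergence: doubling the direction grid
  f288 <- mode_formfactor_amplitude(ch, md, a = 10, Q = Q, n_dirs = 288)
  expect_lt(max(abs(f$A - f288$A)), 1e-4)
})

test_that("NM ISF reduces to diffusion, normalizes, and ignores S_l scaling", {
  ens <- generate_ensemble(2, n_res = 60, seed = 6, excluded_volume = FALSE)
  q <- nse_q
  nm <- nm_model(ens, q = q, eta = 1.1, T = 295)
  t <- c(0, 1, 10, 80)
  # A = 0 (a = 0) and Dr = 0: pure translational diffusion
  isf <- nm_isf(nm, q, t, Dt = 4, tau_nm = 7, a = 0, Dr = 0)
  expect_equal(isf, exp(-outer(q^2 * 4, t)), tolerance = 1e-12)
  # t = 0 is exactly 1
  expect_equal(unname(nm_isf(nm, q, 0, Dt = 4, tau_nm = 7, a = 8)), rep(1, 5))
  # overall S_l normalization cancels in the ratio
  nm2 <- nm
  nm2$per_chain <- lapply(nm$per_chain, function(pc) {
    pc$sl$S <- pc$sl$S * 37.5
    pc
  })
  expect_equal(nm_isf(nm2, q, t, Dt = 4, tau_nm = 7, a = 8),
               nm_isf(nm, q, t, Dt = 4, tau_nm = 7, a = 8), tolerance = 1e-12)
})

test_that("long-time NM decay at small q is governed by q^2 Dt", {
  ens <- generate_ensemble(2, n_res = 60, seed = 16, excluded_volume = FALSE)
  q <- 0.05
  nm <- nm_model(ens, q = q, eta = 1.1, T = 295)
  tlate <- seq(3 / (2 * nm$Dr), 3 / (2 * nm$Dr) + 60, length.out = 8)
  isf <- nm_isf(nm, q, tlate, Dt = 4, tau_nm = 7, a = 6)
  slope <- -coef(lm(log(isf) ~ tlate))[[2]]
  expect_lt(abs(slope / (q^2 * 4) - 1), 0.05)
})

test_that("ensemble ISF averaging is linear in the population weights", {
  ens <- generate_ensemble(2, n_res = 50, seed = 26, excluded_volume = FALSE)
  q <- c(0.08, 0.14); t <- c(1, 20)
  w <- c(0.25, 0.75)
  enw <- bead_ensemble(ens$chains, w)
  nm_w <- nm_model(enw, q = q, eta = 1.1, T = 295)
  parts <- lapply(1:2, function(i) {
    nm_i <- nm_model(bead_ensemble(ens$chains[i], 1), q = q, eta = 1.1,
                     T = 295, Dr = nm_w$Dr)
    nm_isf(nm_i, q, t, Dt = 4, tau_nm = 7, a = 6)
  })
  expect_equal(nm_isf(nm_w, q, t, Dt = 4, tau_nm = 7, a = 6),
               w[1] * parts[[1]] + w[2] * parts[[2]], tolerance = 1e-12)
})

test_that("global NM fit recovers (RMSD, tau_NM, H) and flags the null case", {
  ens <- generate_ensemble(3, n_res = 169, target_nu = 0.53, seed = 5)
  nm <- nm_model(ens, q = nse_q, eta = 1.1, T = 295)
  ds <- make_nse_nm(nm, rmsd = 6, tau_nm = 7, H = 1, D0t = 4.5,
                    noise_frac = 0.02, seed = 12)
  f <- fit_nse_nm(ds, nm, D0t = 4.5)
  expect_lt(abs(f$rmsd / 6 - 1), 0.15)
  expect_lt(abs(f$tau_nm / 7 - 1), 0.15)
  expect_lt(abs(f$H / 1 - 1), 0.15)

  # zero-amplitude data: fitted RMSD consistent with 0, tau flagged
  ds0 <- make_nse_nm(nm, rmsd = 0, tau_nm = 7, H = 1, D0t = 4.5,
                     noise_frac = 0.02, seed = 13)
  f0 <- fit_nse_nm(ds0, nm, D0t = 4.5)
  expect_false(f0$tau_nm_identifiable)
  expect_lt(f0$rmsd, 1)

  # single-chain ensemble equals the direct chain fit (weight degeneracy)
  one <- bead_ensemble(ens$chains[1], 1)
  nm1 <- nm_model(one, q = nse_q, eta = 1.1, T = 295, Dr = nm$Dr)
  nm3 <- nm_model(bead_ensemble(ens$chains[c(1, 1, 1)], c(0.2, 0.3, 0.5)),
                  q = nse_q, eta = 1.1, T = 295, Dr = nm$Dr)
  ds1 <- make_nse_nm(nm1, rmsd = 6, tau_nm = 7, H = 1, D0t = 4.5,
                     noise_frac = 0.02, seed = 14)
  f1 <- fit_nse_nm(ds1, nm1, D0t = 4.5)
  f3 <- fit_nse_nm(ds1, nm3, D0t = 4.5)
  expect_equal(f3$rmsd, f1$rmsd, tolerance = 1e-6)
  expect_equal(f3$tau_nm, f1$tau_nm, tolerance = 1e-6)
})

test_that("Brownian-oscillator friction follows its defining relations", {
  b <- brownian_friction(rmsd = 2, tau = 7, T = 295)
  expect_equal(b$k, 1 / 4)                       # kBT / RMSD^2 in thermal units
  expect_equal(b$zeta, 7 / 4)
  # doubling RMSD quarters zeta at fixed tau
  expect_equal(brownian_friction(4, 7)$zeta, b$zeta / 4)
  # round trip zeta * RMSD^2 / (kBT tau) = 1
  expect_equal(b$zeta * 2^2 / 7, 1, tolerance = 1e-12)
  # unit oracle: RMSD = 1 A at 295 K -> k = kBT/A^2 = 4.0729e-21 J / 1e-20 m^2
  k1 <- brownian_friction(1, 7, T = 295)
  expect_equal(k1$k_SI, 1.380649e-23 * 295 / 1e-20, tolerance = 1e-12)
  expect_error(brownian_friction(0, 7), "must be > 0")
})
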