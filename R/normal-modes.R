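#' Anisotropic network model modes of a bead chain
#'
#' Builds the ANM Hessian (unit spring constant; pairs within the cutoff
#' interact through the standard parallel-projection block), diagonalizes
#' it, verifies the six-fold rigid-body null space and returns the lowest
#' `n_modes` nontrivial eigenvectors.  The spring constant is absorbed into
#' the mode amplitude downstream: only displacement patterns matter.
#'
#' @param chain a [bead_chain()]
#' @param cutoff interaction cutoff \[Angstrom\]; default 15 A, the common
#'   C-alpha elastic-network choice.  The cutoff must comfortably reach the
#'   i+3 neighbor (up to 3 x bond apart on an extended segment), otherwise
#'   torsions about interior bonds cost no energy and spurious zero modes
#'   appear
#' @param n_modes number of nontrivial modes to keep (default 10)
#' @return object of class `anm_modes`: `vectors` (3N x n_modes,
#'   orthonormal, ascending eigenvalue), `values`, `cutoff`, `n_modes`
#' @export
anm_modes <- function(chain, cutoff = 15, n_modes = 10) {
  stopifnot(inherits(chain, "bead_chain"))
  xyz <- chain$coords
  N <- nrow(xyz)
  if (3 * N - 6 < n_modes)
    stop("chain too short for the requested number of modes")
  H <- matrix(0, 3 * N, 3 * N)
  cut2 <- cutoff^2
  for (i in seq_len(N - 1)) {
    ii <- 3 * i - 2:0
    for (j in (i + 1):N) {
      rv <- xyz[j, ] - xyz[i, ]
      r2 <- sum(rv^2)
      if (r2 <= cut2) {
        blk <- -outer(rv, rv) / r2
        jj <- 3 * j - 2:0
        H[ii, jj] <- blk
        H[jj, ii] <- blk
        H[ii, ii] <- H[ii, ii] - blk
        H[jj, jj] <- H[jj, jj] - blk
      }
    }
  }
  e <- eigen(H, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(3 * N)), drop = FALSE]
  nzero <- sum(vals < 1e-8 * max(vals))
  if (nzero > 6)
    stop(sprintf(
      "%d zero modes (> 6): disconnected contact graph or free internal mechanisms; increase the cutoff",
      nzero))
  structure(list(vectors = vecs[, 7:(6 + n_modes), drop = FALSE],
                 values = vals[7:(6 + n_modes)],
                 all_values = vals, cutoff = cutoff, n_modes = n_modes),
            class = "anm_modes")
}

#' @export
print.anm_modes <- function(x, ...) {
  cat(sprintf("<anm_modes> %d nontrivial modes, cutoff %.2f A, eigenvalues %s\n",
              x$n_modes, x$cutoff,
              paste(signif(x$values, 3), collapse = " ")))
  invisible(x)
}

# spherical Bessel j_l(x), vectorized in x
.sph_bessel <- function(l, x) {
  out <- numeric(length(x))
  tiny <- x < 1e-8
  out[tiny] <- if (l == 0) 1 else 0
  xs <- x[!tiny]
  if (length(xs)) out[!tiny] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  out
}

# orthonormal complex spherical harmonics Y_lm for m = 0..l;
# returns (l+1) x npts complex matrix.  pracma::legendre supplies the
# associated Legendre functions (Condon-Shortley phase included).
.ylm <- function(l, costh, phi) {
  P <- pracma::legendre(l, costh)
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
  m <- 0:l
  nrm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  (P * nrm) * exp(1i * outer(m, phi))
}

#' Multipole expansion of the static structure
#'
#' Partial-wave amplitudes of the coherent scattering of a rigid bead
#' model,
#' \deqn{S_l(Q) = 4\pi \sum_m \Big|\sum_i b_i\, j_l(Q r_i)\,
#'   Y_{lm}(\Omega_i)\Big|^2,}
#' with coordinates re-centered to the scattering-length center of mass
#' (the rotational term of the rigid-body ISF assumes a body-fixed origin).
#' In this normalization \eqn{\sum_l S_l(Q)} equals the Debye double sum
#' exactly once l is summed to convergence.
#'
#' @param chain a [bead_chain()]
#' @param Q momentum transfer grid \[1/Angstrom\]
#' @param lmax highest multipole order; default `ceiling(Q_max r_max) + 10`,
#'   capped at 60
#' @return object of class `multipole_table`: matrix `S` ((lmax+1) x
#'   length(Q)), `Q`, `lmax`
#' @export
multipole_sl <- function(chain, Q, lmax = NULL) {
  stopifnot(inherits(chain, "bead_chain"))
  b <- chain$b
  xyz <- sweep(chain$coords, 2, colSums(chain$coords * b) / sum(b))
  r <- sqrt(rowSums(xyz^2))
  if (is.null(lmax)) lmax <- min(ceiling(max(Q) * max(r)) + 10, 60)
  costh <- ifelse(r > 0, xyz[, 3] / r, 1)
  phi <- atan2(xyz[, 2], xyz[, 1])
  S <- matrix(0, lmax + 1, length(Q),
              dimnames = list(paste0("l", 0:lmax), NULL))
  for (l in 0:lmax) {
    Y <- .ylm(l, costh, phi)
    w <- c(1, rep(2, l))               # fold m and -m together
    for (iq in seq_along(Q)) {
      A <- Y %*% (b * .sph_bessel(l, Q[iq] * r))
      S[l + 1, iq] <- 4 * pi * sum(w * Mod(A)^2)
    }
  }
  structure(list(S = S, Q = Q, lmax = lmax), class = "multipole_table")
}

# deterministic spherical Fibonacci direction grid (n x 3 unit vectors)
.fib_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Normal-mode dynamic form factors and amplitude A(q)
#'
#' Computes the static form factor \eqn{F(q) = \langle|\sum_k b_k
#' e^{i q\cdot r_k}|^2\rangle} and the mode form factors
#' \deqn{F_\alpha(q) = \langle|\sum_k b_k e^{i q\cdot r_k}
#'  (q\cdot e_k^\alpha)|^2\rangle}
#' with a deterministic spherical-Fibonacci orientational average, and the
#' internal-mode amplitude
#' \deqn{A(q) = \frac{a^2\sum_\alpha F_\alpha}{F + a^2\sum_\alpha F_\alpha}}
#' for a common amplitude a applied to all (equally weighted) modes.  The
#' amplitude enters quadratically, so A scales as a^2 for small a and
#' A -> 0 as a -> 0.
#'
#' @param chain a [bead_chain()]
#' @param modes an [anm_modes()]
#' @param a common mode amplitude \[Angstrom\]; per-atom RMSD of the summed
#'   displacement field is `a * sqrt(n_modes / N)`
#' @param Q momentum transfer grid \[1/Angstrom\]
#' @param n_dirs number of orientational-average directions (default 144)
#' @return list with `A` (length(Q)), `Fq`, `Falpha` (n_modes x length(Q)),
#'   `Q`, `a`
#' @export
mode_formfactor_amplitude <- function(chain, modes, a, Q, n_dirs = 144) {
  stopifnot(inherits(chain, "bead_chain"), inherits(modes, "anm_modes"),
            a >= 0)
  ff <- .mode_formfactors(chain, modes, Q, n_dirs)
  list(A = .amplitude_from_ff(ff, a), Fq = ff$Fq, Falpha = ff$Falpha,
       Q = Q, a = a)
}

# orientationally averaged F(q) and F_alpha(q); a-independent, reusable
.mode_formfactors <- function(chain, modes, Q, n_dirs = 144) {
  xyz <- chain$coords
  b <- chain$b
  nm <- modes$n_modes
  dirs <- .fib_directions(n_dirs)
  proj <- xyz %*% t(dirs)                   # N x n_dirs bead projections
  Fq <- numeric(length(Q))
  Falpha <- matrix(0, nm, length(Q))
  evec <- lapply(seq_len(nm), function(m)
    matrix(modes$vectors[, m], ncol = 3, byrow = TRUE))   # N x 3 each
  edirs <- lapply(evec, function(E) E %*% t(dirs))        # N x n_dirs
  for (iq in seq_along(Q)) {
    ph <- exp(1i * Q[iq] * proj)            # N x n_dirs
    Fq[iq] <- mean(Mod(colSums(b * ph))^2)
    for (m in seq_len(nm))
      Falpha[m, iq] <- mean(Mod(colSums(b * ph * (Q[iq] * edirs[[m]])))^2)
  }
  list(Fq = Fq, Falpha = Falpha)
}

.amplitude_from_ff <- function(ff, a) {
  s <- a^2 * colSums(ff$Falpha)
  s / (ff$Fq + s)
}

#' Precomputed normal-mode model of an ensemble
#'
#' Bundles, for every chain of an ensemble, the multipole table and the
#' mode form factors on a fixed q grid, together with the
#' population-weighted rotational diffusion coefficient — everything the
#' rigid-body-plus-normal-mode ISF needs that does not depend on the fit
#' parameters.
#'
#' @param ens a [bead_ensemble()]
#' @param q momentum-transfer grid the NSE data live on \[1/Angstrom\]
#' @param eta,T solvent viscosity \[mPa s\] and temperature \[K\] for the
#'   hydrodynamic stage
#' @param n_modes nontrivial ANM modes per chain (default 10)
#' @param cutoff ANM cutoff \[Angstrom\]
#' @param bead_radius hydrodynamic bead radius \[Angstrom\]
#' @param n_dirs orientational-average grid size
#' @param lmax multipole cutoff (default rule `ceiling(Q r_max) + 10`,
#'   capped at 60)
#' @param Dr optional fixed rotational diffusion \[1/ns\]; default is the
#'   population-weighted rigid-body value of the ensemble
#' @return object of class `nm_model`
#' @export
nm_model <- function(ens, q, eta, T, n_modes = 10,
                     cutoff = 15,
                     bead_radius = 1.9, n_dirs = 144, lmax = NULL,
                     Dr = NULL) {
  stopifnot(inherits(ens, "bead_ensemble"))
  if (is.null(Dr)) Dr <- ensemble_hydro(ens, eta, T, bead_radius)$Dr
  per_chain <- lapply(ens$chains, function(ch) {
    md <- anm_modes(ch, cutoff, n_modes)
    list(sl = multipole_sl(ch, q, lmax),
         ff = .mode_formfactors(ch, md, q, n_dirs),
         n_beads = nrow(ch$coords))
  })
  structure(list(per_chain = per_chain, weights = ens$weights, q = q,
                 Dr = Dr, n_modes = n_modes, eta = eta, T = T,
                 n_beads = per_chain[[1]]$n_beads),
            class = "nm_model")
}

#' @export
print.nm_model <- function(x, ...) {
  cat(sprintf(
    "<nm_model> %d chains, %d modes each, Dr = %.5f 1/ns, q grid of %d points\n",
    length(x$per_chain), x$n_modes, x$Dr, length(x$q)))
  invisible(x)
}

#' Rigid-body plus normal-mode intermediate scattering function
#'
#' Per chain,
#' \deqn{\frac{I(q,t)}{I(q,0)} = \big(1 - A(q) + A(q) e^{-t/\tau_{NM}}\big)
#'   e^{-q^2 D_t t}\frac{\sum_l S_l(q) e^{-l(l+1)D_r t}}{\sum_l S_l(q)},}
#' i.e. translational and rotational diffusion of the rigid conformer
#' modulated by overdamped displacements along the normal modes with a
#' common relaxation time.  The ensemble ISF is the population-weighted
#' average of the per-chain ISFs.  The S_l enter as a ratio, so their
#' overall normalization cancels.
#'
#' @param model an [nm_model()]
#' @param q momentum transfers; must be members of the model grid
#' @param t times \[ns\]
#' @param Dt effective translational diffusion \[Angstrom^2/ns\], scalar or
#'   per q
#' @param tau_nm common normal-mode relaxation time \[ns\]
#' @param a common mode amplitude \[Angstrom\]
#' @param Dr rotational diffusion \[1/ns\]; default from the model
#' @return matrix length(q) x length(t) (dropped to vector when scalar)
#' @export
nm_isf <- function(model, q, t, Dt, tau_nm, a, Dr = model$Dr) {
  stopifnot(inherits(model, "nm_model"))
  iqs <- match(q, model$q)
  if (anyNA(iqs)) stop("q values must be on the model grid")
  Dt <- rep_len(Dt, length(q))
  out <- matrix(0, length(q), length(t))
  for (ic in seq_along(model$per_chain)) {
    pc <- model$per_chain[[ic]]
    Sl <- pc$sl$S[, iqs, drop = FALSE]
    l <- 0:pc$sl$lmax
    rot_rates <- l * (l + 1) * Dr
    A <- .amplitude_from_ff(pc$ff, a)[iqs]
    for (it in seq_along(t)) {
      rot <- colSums(Sl * exp(-rot_rates * t[it])) / colSums(Sl)
      intern <- 1 - A + A * exp(-t[it] / tau_nm)
      out[, it] <- out[, it] + model$weights[ic] *
        intern * exp(-q^2 * Dt * t[it]) * rot
    }
  }
  drop(out)
}

#' Global normal-mode fit of an NSE dataset
#'
#' Weighted global fit across all (q, t) points of the ensemble
#' rigid-body-plus-normal-mode ISF with D0t fixed (from DLS or the
#' hydrodynamic stage) and three free parameters: the common mode amplitude
#' (reported as per-atom RMSD \eqn{a\sqrt{n_{modes}/N}}), the common
#' relaxation time tau_NM, and the q-independent hydrodynamic factor H
#' entering \eqn{D_t(q) = D_{0,t} H / S(q)}.
#'
#' When the fitted amplitude is consistent with zero the relaxation time is
#' unidentifiable; this is flagged (`tau_nm_identifiable = FALSE`).
#'
#' @param ds an [nse_dataset()]
#' @param model an [nm_model()] built on the q grid of `ds`
#' @param D0t fixed dilute-limit translational diffusion \[Angstrom^2/ns\]
#' @param sq optional `structure_factor_curve`; NULL means S = 1
#' @param rmsd0,tau0,H0 starting values
#' @return object of class `nm_fit`: `rmsd`, `tau_nm`, `H` with standard
#'   errors, `chi2_red`, `tau_nm_identifiable`
#' @export
fit_nse_nm <- function(ds, model, D0t, sq = NULL, rmsd0 = 2, tau0 = 7,
                       H0 = 1) {
  stopifnot(inherits(ds, "nse_dataset"), inherits(model, "nm_model"))
  d <- ds$data[ds$data$fnorm > 0, ]
  qs <- sort(unique(d$q))
  ts <- sort(unique(d$t))
  idx <- cbind(match(d$q, qs), match(d$t, ts))
  amp_scale <- sqrt(model$n_modes / model$n_beads)   # rmsd = a * amp_scale
  modelfun <- function(a, tau_nm, H) {
    Dt <- effective_diffusion(D0t, H, sq, qs)
    m <- nm_isf(model, qs, ts, Dt, tau_nm, a)
    matrix(m, length(qs), length(ts))[idx]
  }
  # A(q) is quadratic in the amplitude, so fit b = a^2: the gradient in b
  # stays finite at zero amplitude and the null case is reachable
  f <- .lm_fit(function(p)
    (d$fnorm - modelfun(sqrt(p[["b"]]), exp(p[["log_tau"]]), p[["H"]])) / d$sigma,
    c(b = (rmsd0 / amp_scale)^2, log_tau = log(tau0), H = H0),
    c(0, log(1e-3), 1e-3), c(Inf, log(1e5), 100), what = "normal-mode")
  tau_nm <- exp(f$par[["log_tau"]])
  a <- sqrt(f$par[["b"]])
  rmsd <- a * amp_scale
  se_rmsd <- if (a > 0) unname(f$se["b"]) * amp_scale / (2 * a) else NA_real_
  identifiable <- is.finite(se_rmsd) && rmsd > 2 * se_rmsd
  structure(list(rmsd = rmsd, se_rmsd = se_rmsd,
                 tau_nm = tau_nm,
                 se_tau_nm = unname(f$se["log_tau"]) * tau_nm,
                 H = f$par[["H"]], se_H = unname(f$se["H"]),
                 chi2_red = f$chi2_red, a = a,
                 tau_nm_identifiable = identifiable,
                 n_modes = model$n_modes, D0t = D0t, Dr = model$Dr),
            class = "nm_fit")
}

#' @export
print.nm_fit <- function(x, ...) {
  cat(sprintf(
    "Normal-mode global fit: RMSD = %.2f +/- %.2f A, tau_NM = %.2f +/- %.2f ns, H = %.3f +/- %.3f\n",
    x$rmsd, x$se_rmsd, x$tau_nm, x$se_tau_nm, x$H, x$se_H))
  cat(sprintf("  reduced chi^2 = %.2f%s\n", x$chi2_red,
              if (!x$tau_nm_identifiable)
                "  [amplitude consistent with 0: tau_NM unidentifiable]" else ""))
  invisible(x)
}

#' Brownian-oscillator friction from RMSD and relaxation time
#'
#' For an overdamped harmonic degree of freedom the mean-square
#' displacement and relaxation time give the force constant
#' \eqn{k = k_B T / RMSD^2} and friction \eqn{\zeta = k_B T \tau / RMSD^2}.
#' Values are reported in thermal units (k_B T / Angstrom^2 and
#' k_B T ns / Angstrom^2) plus SI equivalents.
#'
#' @param rmsd root-mean-square displacement \[Angstrom\]
#' @param tau relaxation time \[ns\]
#' @param T temperature \[K\] (used only for the SI conversions)
#' @return object of class `brownian_friction`: `zeta` \[k_B T ns /
#'   Angstrom^2\], `k` \[k_B T / Angstrom^2\], `zeta_SI` \[kg/s\],
#'   `k_SI` \[N/m\]
#' @export
brownian_friction <- function(rmsd, tau, T = 295) {
  if (rmsd <= 0 || tau <= 0) stop("rmsd and tau must be > 0")
  k <- 1 / rmsd^2
  zeta <- tau / rmsd^2
  kBT <- .kB * T
  structure(list(zeta = zeta, k = k,
                 zeta_SI = kBT * tau * 1e-9 / (rmsd * 1e-10)^2,
                 k_SI = kBT / (rmsd * 1e-10)^2,
                 rmsd = rmsd, tau = tau, T = T),
            class = "brownian_friction")
}

#' @export
print.brownian_friction <- function(x, ...) {
  cat(sprintf(
    "Brownian oscillator: k = %.4f kBT/A^2 (%.3g N/m), zeta = %.2f kBT ns/A^2 (%.3g kg/s)\n",
    x$k, x$k_SI, x$zeta, x$zeta_SI))
  invisible(x)
}
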