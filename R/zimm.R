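#' Zimm / ZIF model parameters
#'
#' Bead-spring polymer state for the Zimm model with hydrodynamic
#' interactions, optionally with internal friction (ZIF).  Derived
#' quantities follow the chain-statistics relations
#' \eqn{R_e = \sqrt{(2\nu+1)(2\nu+2)}\, R_G} and \eqn{l = R_e / N^\nu};
#' the mode spectrum is
#' \eqn{\tau_p = \eta R_e^3 / (\sqrt{3\pi}\, k_B T)\, p^{-3\nu}}, shifted by
#' a mode-independent internal-friction time for the ZIF variant,
#' \eqn{\tau_p^{ZIF} = \tau_p + \tau_i}.
#'
#' @param rg radius of gyration \[Angstrom\] (from the SAS stage)
#' @param nu scaling exponent
#' @param eta solvent viscosity \[mPa s\]
#' @param T temperature \[K\]
#' @param N bead count (default 20, ~8 residues per bead for a 169-residue
#'   chain); results are insensitive to N by scale invariance
#' @param tau_i internal friction time \[ns\], 0 for the pure Zimm model
#' @param pmax mode-sum cutoff, default N
#' @return object of class `zimm_params` with derived `Re`, `l`, `tau_p`
#' @export
zimm_params <- function(rg, nu, eta, T, N = 20, tau_i = 0, pmax = N) {
  stopifnot(rg > 0, nu > 0, nu <= 1, eta > 0, T > 0, N >= 1, tau_i >= 0)
  Re <- sqrt((2 * nu + 1) * (2 * nu + 2)) * rg
  l <- Re / N^nu
  tau1 <- eta * 1e-3 * (Re * 1e-10)^3 / (sqrt(3 * pi) * .kB * T) * 1e9  # ns
  p <- seq_len(pmax)
  structure(list(rg = rg, nu = nu, eta = eta, T = T, N = N, pmax = pmax,
                 Re = Re, l = l, tau_i = tau_i,
                 tau_p = tau1 * p^(-3 * nu)),
            class = "zimm_params")
}

#' @export
print.zimm_params <- function(x, ...) {
  cat(sprintf(
    "Zimm%s chain: N = %d, RG = %.1f A, nu = %.3f, Re = %.1f A, l = %.2f A\n",
    if (x$tau_i > 0) " (internal friction)" else "", x$N, x$rg, x$nu, x$Re, x$l))
  cat(sprintf("  tau_1 = %.1f ns%s   (eta = %g mPa s, T = %g K)\n",
              x$tau_p[1],
              if (x$tau_i > 0) sprintf(", tau_i = %.1f ns", x$tau_i) else "",
              x$eta, x$T))
  invisible(x)
}

#' Zimm mode relaxation times
#'
#' @param params a [zimm_params()]
#' @param with_internal_friction add tau_i to every mode time (the ZIF
#'   spectrum)
#' @return tau_p \[ns\] for p = 1..pmax
#' @export
zimm_mode_times <- function(params, with_internal_friction = FALSE) {
  stopifnot(inherits(params, "zimm_params"))
  params$tau_p + if (with_internal_friction) params$tau_i else 0
}

# mode-sum core: returns matrix of ISF values (length(q) x length(t)),
# already normalized to its t = 0 value, including exp(-q^2 Dt t).
# Dt: vector along q [A^2/ns].
.zimm_isf_core <- function(params, q, t, Dt, tau_i) {
  N <- params$N; nu <- params$nu; l <- params$l; Re <- params$Re
  p <- seq_len(params$pmax)
  taup <- params$tau_p + tau_i
  n <- seq_len(N)
  # discrete bead-spring eigenfunctions: half-integer bead positions make
  # the mode sum vanish identically for N = 1 (no internal modes)
  cosmat <- cos(pi * outer(n - 0.5, p) / N)            # N x pmax
  B0 <- abs(outer(n, n, "-"))^(2 * nu) * l^2           # t = 0 static part
  pref <- 4 * Re^2 / pi^2
  pw <- p^(-(2 * nu + 1))
  out <- matrix(0, length(q), length(t))
  q2 <- q^2
  denom <- vapply(q2, function(qq) sum(exp(-qq * B0 / 6)), 0)
  for (it in seq_along(t)) {
    relax <- pw * (1 - exp(-t[it] / taup))
    B <- B0 + pref * (cosmat %*% (t(cosmat) * relax))
    for (iq in seq_along(q)) {
      out[iq, it] <- exp(-q2[iq] * Dt[iq] * t[it]) *
        sum(exp(-q2[iq] * B / 6)) / denom[iq]
    }
  }
  out
}

#' Intermediate scattering function of the Zimm model
#'
#' Normalized coherent ISF of a bead-spring chain with hydrodynamic
#' interactions: center-of-mass diffusion times the internal mode sum,
#' \deqn{I(q,t) = e^{-q^2 D_t t} \frac1N \sum_{n,m} e^{-q^2 B(n,m,t)/6},}
#' \deqn{B(n,m,t) = |n-m|^{2\nu} l^2 + \frac{4R_e^2}{\pi^2}
#'  \sum_{p=1}^{p_{max}} \frac{1}{p^{2\nu+1}}
#'  \cos\frac{\pi p n}{N}\cos\frac{\pi p m}{N}(1 - e^{-t/\tau_p}),}
#' evaluated as the ratio to its t = 0 value so that the result matches the
#' measured I(q,t)/I(q,0) exactly at t = 0.
#'
#' @param params a [zimm_params()]; its `tau_i` is ignored here (pure Zimm)
#' @param q momentum transfer(s) \[1/Angstrom\], > 0
#' @param t times \[ns\], >= 0
#' @param Dt effective translational diffusion \[Angstrom^2/ns\]; scalar or
#'   one value per q (see [effective_diffusion()])
#' @return matrix length(q) x length(t) of I(q,t)/I(q,0); drops to a vector
#'   if either argument is scalar
#' @export
zimm_isf <- function(params, q, t, Dt) {
  stopifnot(inherits(params, "zimm_params"), all(q > 0), all(t >= 0))
  Dt <- rep_len(Dt, length(q))
  drop(.zimm_isf_core(params, q, t, Dt, tau_i = 0))
}

#' Intermediate scattering function of the ZIF model
#'
#' Identical to [zimm_isf()] with every mode time shifted by the internal
#' friction time, tau_p + tau_i.  With tau_i = 0 it equals the Zimm ISF;
#' tau_i -> infinity freezes the internal modes, leaving pure
#' center-of-mass decay exp(-q^2 Dt t).
#'
#' @inheritParams zimm_isf
#' @param tau_i internal friction time \[ns\]; default taken from `params`
#' @export
zif_isf <- function(params, q, t, Dt, tau_i = params$tau_i) {
  stopifnot(inherits(params, "zimm_params"), all(q > 0), all(t >= 0),
            tau_i >= 0)
  Dt <- rep_len(Dt, length(q))
  drop(.zimm_isf_core(params, q, t, Dt, tau_i = tau_i))
}

#' Structure-factor-corrected effective diffusion
#'
#' \eqn{D_t(q) = D_{0,t} H / S(q)}: the dilute-limit translational
#' diffusion corrected for hydrodynamic (H) and interparticle (S(q))
#' interactions.  S is interpolated onto the requested q grid with the
#' same log-linear dialect as the SAS stage; S = 1 is assumed when no
#' structure factor is supplied.
#'
#' @param D0t dilute-limit translational diffusion \[Angstrom^2/ns\]
#' @param H q-independent hydrodynamic factor
#' @param sq a `structure_factor_curve` (or list with `q`, `S`), or NULL
#' @param q momentum transfer grid \[1/Angstrom\]
#' @return Dt(q) \[Angstrom^2/ns\]
#' @export
effective_diffusion <- function(D0t, H, sq = NULL, q) {
  if (is.null(sq)) return(rep(D0t * H, length(q)))
  S <- .interp_logy(sq$q, sq$S, q)
  if (anyNA(S))
    stop("requested q outside the structure-factor support; not extrapolating")
  D0t * H / S
}

#' Model-free stretched-exponential analysis of NSE spectra
#'
#' Fits \eqn{\exp(-(\Gamma t)^\beta)} per q (amplitude fixed to 1) and
#' reports effective diffusion coefficients \eqn{D_{eff} = \Gamma/q^2} and
#' stretching exponents beta, plus their unweighted mean over q.
#' Ideal Zimm dynamics gives beta ~ 0.85; pure diffusion gives beta = 1.
#'
#' @param ds an [nse_dataset()]
#' @param min_points q-groups with fewer time points are skipped with a
#'   warning
#' @return object of class `stretched_exp_result`: data.frame `per_q` with
#'   columns `q`, `Deff`, `beta`, `se_Deff`, `se_beta`, `chi2_red`, and
#'   scalar `beta_mean`
#' @export
fit_stretched_exponential <- function(ds, min_points = 5) {
  stopifnot(inherits(ds, "nse_dataset"))
  d <- ds$data[ds$data$fnorm > 0, ]
  out <- lapply(split(d, d$q), function(g) {
    qv <- g$q[1]
    if (nrow(g) < min_points) {
      warning(sprintf("q = %g: only %d points, skipped", qv, nrow(g)))
      return(NULL)
    }
    tt <- g$t[g$t > 0]; ff <- g$fnorm[g$t > 0]; sg <- g$sigma[g$t > 0]
    # moment-based start: Gamma from the time where f ~ 1/e
    g0 <- 1 / tt[which.min(abs(ff - exp(-1)))]
    par <- c(log_gamma = log(max(g0, 1e-6)), beta = 0.9)
    f <- .lm_fit(function(p) {
      b <- min(max(p[["beta"]], 0.05), 1)
      (ff - exp(-(exp(p[["log_gamma"]]) * tt)^b)) / sg
    }, par, c(-Inf, 0.05), c(Inf, 1), what = "stretched_exp")
    gamma <- exp(f$par[["log_gamma"]])
    data.frame(q = qv, Deff = gamma / qv^2, beta = f$par[["beta"]],
               se_Deff = unname(f$se["log_gamma"]) * gamma / qv^2,
               se_beta = unname(f$se["beta"]), chi2_red = f$chi2_red)
  })
  per_q <- do.call(rbind, out)
  rownames(per_q) <- NULL
  structure(list(per_q = per_q, beta_mean = mean(per_q$beta)),
            class = "stretched_exp_result")
}

#' @export
print.stretched_exp_result <- function(x, ...) {
  cat("Stretched-exponential (KWW) fits per q:\n")
  print(transform(x$per_q, Deff = signif(Deff, 4), beta = round(beta, 3),
                  se_Deff = signif(se_Deff, 2), se_beta = signif(se_beta, 2),
                  chi2_red = signif(chi2_red, 3)), row.names = FALSE)
  cat(sprintf("<beta> = %.3f (unweighted mean over %d q values)\n",
              x$beta_mean, nrow(x$per_q)))
  invisible(x)
}

#' Global ZIF fit of an NSE dataset
#'
#' Single weighted fit across all (q, t) points with the chain structure
#' (R_G, nu from SAS), the dilute diffusion D0t and the structure factor
#' S(q) held fixed, and the hydrodynamic factor H (shared across the whole
#' dataset) plus the internal friction time tau_i free.  tau_i is
#' parameterized internally as log(tau_i) to enforce positivity; a fit
#' collapsing to the lower bound is reported as an upper limit
#' (`tau_i_bound = TRUE`).  The tau_i = 0 (pure Zimm) fit is evaluated
#' alongside for model comparison.
#'
#' @param ds an [nse_dataset()]
#' @param params a [zimm_params()] built from the SAS-stage (R_G, nu) and
#'   the solvent (eta, T)
#' @param D0t fixed dilute-limit diffusion \[Angstrom^2/ns\]
#' @param sq optional `structure_factor_curve`; NULL means S = 1
#' @param tau_i0,H0 starting values
#' @param fit_zimm also fit the pure-Zimm alternative (default TRUE)
#' @return object of class `zif_fit`: `tau_i`, `H`, `se`, `chi2_red`,
#'   `per_q` residual summary, and `zimm` (H, chi2_red of the tau_i = 0 fit)
#' @export
fit_nse_zif <- function(ds, params, D0t, sq = NULL, tau_i0 = 20, H0 = 1,
                        fit_zimm = TRUE) {
  stopifnot(inherits(ds, "nse_dataset"), inherits(params, "zimm_params"))
  d <- ds$data[ds$data$fnorm > 0, ]
  qs <- sort(unique(d$q))
  ts <- sort(unique(d$t))
  idx <- cbind(match(d$q, qs), match(d$t, ts))
  model <- function(tau_i, H) {
    Dt <- effective_diffusion(D0t, H, sq, qs)
    m <- .zimm_isf_core(params, qs, ts, Dt, tau_i)
    m[idx]
  }
  fit1 <- .lm_fit(function(p)
    (d$fnorm - model(exp(p[["log_tau_i"]]), p[["H"]])) / d$sigma,
    c(log_tau_i = log(tau_i0), H = H0),
    c(log(1e-3), 1e-3), c(log(1e5), 100), what = "ZIF")
  tau_i <- exp(fit1$par[["log_tau_i"]])
  at_bound <- tau_i <= 1.5e-3
  res <- (d$fnorm - model(tau_i, fit1$par[["H"]])) / d$sigma
  per_q <- aggregate(list(chi2_red = res^2), list(q = d$q), mean)
  zimm <- NULL
  if (fit_zimm) {
    fz <- .lm_fit(function(p) (d$fnorm - model(0, p[["H"]])) / d$sigma,
                  c(H = H0), 1e-3, 100, what = "Zimm")
    zimm <- list(H = fz$par[["H"]], se_H = unname(fz$se["H"]),
                 chi2_red = fz$chi2_red)
  }
  structure(list(
    tau_i = tau_i,
    se_tau_i = unname(fit1$se["log_tau_i"]) * tau_i,
    H = fit1$par[["H"]], se_H = unname(fit1$se["H"]),
    chi2_red = fit1$chi2_red, per_q = per_q,
    tau_i_bound = at_bound, zimm = zimm, D0t = D0t,
    params = params), class = "zif_fit")
}

#' @export
print.zif_fit <- function(x, ...) {
  cat(sprintf("ZIF global fit: tau_i = %.1f +/- %.1f ns%s,  H = %.3f +/- %.3f,  reduced chi^2 = %.2f\n",
              x$tau_i, x$se_tau_i,
              if (x$tau_i_bound) " (upper limit, hit lower bound)" else "",
              x$H, x$se_H, x$chi2_red))
  if (!is.null(x$zimm))
    cat(sprintf("  pure Zimm (tau_i = 0): H = %.3f, reduced chi^2 = %.2f\n",
                x$zimm$H, x$zimm$chi2_red))
  invisible(x)
}
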