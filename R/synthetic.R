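#' Ground-truth record for synthetic data
#'
#' Every generator is a pure function of (truth, seed); the generating
#' parameters travel with the dataset (in its `meta`) so recovery tests and
#' provenance records can always reach them.
#'
#' @param model generating model name (`"gauss_coil"`, `"zif"`, `"nm"`, ...)
#' @param seed RNG seed used
#' @param noise_frac relative noise level
#' @param ... named generating parameters (rg, nu, tau_i, tau_nm, rmsd, H,
#'   D0t, Dr, phi, r_hs, ...)
#' @return list of class `ground_truth`
#' @export
ground_truth <- function(model, seed, noise_frac, ...) {
  structure(c(list(model = model, seed = seed, noise_frac = noise_frac),
              list(...)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  flds <- setdiff(names(x), "model")
  cat(sprintf("<ground_truth:%s> %s\n", x$model,
              paste(flds, vapply(x[flds], function(v)
                paste(signif(unlist(v), 4), collapse = ","), ""),
                sep = "=", collapse = "  ")))
  invisible(x)
}

# default instrument-like grids
.default_saxs_q <- function() exp(seq(log(0.01), log(0.7), length.out = 120))
.default_nse_q <- function() c(0.05, 0.08, 0.11, 0.14, 0.17)
.default_nse_t <- function() exp(seq(log(0.1), log(150), length.out = 25))

#' Synthetic SAXS curve from the generalized Gaussian coil
#'
#' Forward model [gauss_coil_formfactor()] with multiplicative Gaussian
#' noise; the sigma column is `noise_frac * I_model` (exact, noise-free).
#'
#' @param rg,nu,scale,background coil parameters
#' @param q momentum-transfer grid (default 120 log-spaced points,
#'   0.01-0.7 1/Angstrom)
#' @param noise_frac relative noise (0 gives the exact model)
#' @param seed RNG seed
#' @return a [scattering_curve()] with the [ground_truth()] in
#'   `meta$ground_truth`
#' @export
make_saxs <- function(rg, nu, scale = 1, background = 0,
                      q = .default_saxs_q(), noise_frac = 0.02, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  I0 <- gauss_coil_formfactor(q, rg, nu, scale, background)
  sigma <- pmax(noise_frac * I0, 1e-12)
  I <- I0 * (1 + noise_frac * rnorm(length(q)))
  if (noise_frac == 0) I <- I0
  scattering_curve(q, I, sigma, meta = list(
    probe = "SAXS",
    ground_truth = ground_truth("gauss_coil", seed, noise_frac, rg = rg,
                                nu = nu, scale = scale,
                                background = background)))
}

# shared NSE noise model: multiplicative Gaussian, sigma floor 1e-3 on I/I0
.noisy_nse <- function(q, t, isf, noise_frac, T, eta, truth) {
  grid <- expand.grid(t = t, q = q)[, c("q", "t")]
  f0 <- as.numeric(t(isf))             # row-major along q blocks
  sigma <- pmax(noise_frac * f0, 1e-3)
  f <- if (noise_frac > 0) f0 * (1 + noise_frac * rnorm(length(f0))) else f0
  nse_dataset(grid$q, grid$t, f, sigma, T = T, eta = eta,
              meta = list(ground_truth = truth))
}

#' Synthetic NSE dataset from the Zimm / ZIF forward model
#'
#' Evaluates the ZIF intermediate scattering function (pure Zimm when
#' `tau_i = 0`) with D_t(q) = D0t H / S(q) and adds multiplicative Gaussian
#' noise with a sigma floor of 1e-3.
#'
#' @param rg,nu,tau_i chain structure and internal friction time \[ns\]
#' @param H hydrodynamic factor
#' @param D0t dilute-limit diffusion \[Angstrom^2/ns\]
#' @param eta,T solvent viscosity \[mPa s\] and temperature \[K\]
#' @param sq optional `structure_factor_curve` (NULL: S = 1)
#' @param N bead count
#' @param q,t acquisition grids (defaults mirror a spin-echo campaign:
#'   5 q in 0.05-0.17 1/Angstrom, 15 log-spaced times 0.1-150 ns)
#' @param noise_frac relative noise
#' @param seed RNG seed
#' @return an [nse_dataset()] with ground truth in `meta`
#' @export
make_nse_zif <- function(rg, nu, tau_i, H, D0t, eta = 1.1, T = 295,
                         sq = NULL, N = 20, q = .default_nse_q(),
                         t = .default_nse_t(), noise_frac = 0.02, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  pars <- zimm_params(rg, nu, eta, T, N = N, tau_i = tau_i)
  Dt <- effective_diffusion(D0t, H, sq, q)
  isf <- matrix(.zimm_isf_core(pars, q, t, Dt, tau_i), length(q), length(t))
  .noisy_nse(q, t, isf, noise_frac, T, eta,
             ground_truth("zif", seed, noise_frac, rg = rg, nu = nu,
                          tau_i = tau_i, H = H, D0t = D0t, N = N))
}

#' Synthetic NSE dataset from the normal-mode forward model
#'
#' Evaluates the ensemble rigid-body-plus-normal-mode ISF of a precomputed
#' [nm_model()] at known (RMSD, tau_NM, H) and adds noise.
#'
#' @param model an [nm_model()] built on the target q grid
#' @param rmsd per-atom RMSD \[Angstrom\] of the mode displacement field
#' @param tau_nm common mode relaxation time \[ns\]
#' @param H hydrodynamic factor
#' @param D0t dilute-limit diffusion \[Angstrom^2/ns\]
#' @param sq optional structure factor
#' @param q,t acquisition grids (q defaults to the model grid)
#' @param noise_frac,seed noise level and seed
#' @return an [nse_dataset()] with ground truth in `meta`
#' @export
make_nse_nm <- function(model, rmsd, tau_nm, H, D0t, sq = NULL,
                        q = model$q, t = .default_nse_t(),
                        noise_frac = 0.02, seed = 1) {
  stopifnot(inherits(model, "nm_model"))
  if (!is.null(seed)) set.seed(seed)
  a <- rmsd / sqrt(model$n_modes / model$n_beads)
  Dt <- effective_diffusion(D0t, H, sq, q)
  isf <- matrix(nm_isf(model, q, t, Dt, tau_nm, a), length(q), length(t))
  .noisy_nse(q, t, isf, noise_frac, model$T, model$eta,
             ground_truth("nm", seed, noise_frac, rmsd = rmsd,
                          tau_nm = tau_nm, H = H, D0t = D0t,
                          Dr = model$Dr, n_modes = model$n_modes))
}

#' Synthetic denaturant condition series
#'
#' Five-condition bundle emulating a chaotropic titration (0, 0.2, 1, 4,
#' 6 M) of a 169-residue disordered protein: a compact, charge-screened
#' start (nu ~ 0.48, strong internal friction) expanding towards a swollen
#' coil (nu ~ 0.53, internal friction at its ~40 ns floor, growing mode
#' amplitudes).  By construction the series is monotone (non-decreasing) in
#' nu and RMSD and non-increasing in tau_i; R_G values are chosen so that
#' the first Zimm mode times match the fitted-structure scale of the
#' denaturant campaign at nominal eta = 1.1 mPa s.  The two highest
#' conditions carry a repulsive Percus-Yevick structure factor; the low
#' conditions use S = 1 (charged-sphere attraction is out of scope).
#'
#' Each condition holds a noisy SAXS curve, a ZIF-generated NSE dataset, a
#' chain ensemble with its normal-mode model and an NM-generated NSE
#' dataset, plus the full ground truth; `manifest` collects the truths.
#'
#' @param seed master seed; per-condition seeds are derived from it
#' @param noise_frac relative noise for SAXS and NSE
#' @param n_chains ensemble pool size per condition
#' @param k_rep representatives kept for the normal-mode stage
#' @param n_res beads per chain
#' @return object of class `condition_series`: list `conditions`, each with
#'   `label`, `truth`, `saxs`, `nse_zif`, `ensemble`, `nm`, `nse_nm`, `sq`;
#'   and a `manifest` data.frame
#' @export
make_condition_series <- function(seed = 1, noise_frac = 0.02,
                                  n_chains = 20, k_rep = 3, n_res = 169) {
  labels <- c("0M", "0.2M", "1M", "4M", "6M")
  rg    <- c(39.0, 36.9, 41.8, 45.7, 50.8)
  nu    <- c(0.48, 0.49, 0.53, 0.53, 0.53)
  tau_i <- c(70, 70, 55, 45, 40)
  H     <- c(1.20, 1.25, 1.10, 1.05, 1.00)
  rmsd  <- c(4.0, 4.0, 5.0, 6.0, 7.0)
  tau_nm <- rep(7, 5)
  rh_ratio <- c(0.95, 1.00, 0.85, 0.78, 0.72)   # compact -> coil-like
  eta <- 1.1; T <- 295
  conditions <- vector("list", 5)
  for (i in 1:5) {
    si <- seed * 1000L + i
    D0t <- stokes_einstein_d(rh_ratio[i] * rg[i], eta, T)
    sq <- if (i >= 4) {
      qs <- .default_saxs_q()
      structure(list(q = qs, S = hard_sphere_sq(qs, 28, 0.06),
                     sigma = rep(1e-4, length(qs))),
                class = "structure_factor_curve")
    } else NULL
    saxs <- make_saxs(rg[i], nu[i], noise_frac = noise_frac, seed = si)
    nse_zif <- make_nse_zif(rg[i], nu[i], tau_i[i], H[i], D0t, eta, T,
                            sq = sq, noise_frac = noise_frac, seed = si + 100L)
    # stiffest attainable walk: ensemble R_G ~ 38 A at 169 beads, matching
    # the size scale of the campaign so that rotational relaxation
    # (tau_r ~ tens of ns) stays separated from tau_NM ~ 7 ns
    ens <- generate_ensemble(n_chains, n_res = n_res, target_nu = 0.546,
                             seed = si + 200L)
    reps <- select_representatives(ens, k_rep)
    nm <- nm_model(reps, q = .default_nse_q(), eta = eta, T = T)
    nse_nm <- make_nse_nm(nm, rmsd[i], tau_nm[i], H[i], D0t, sq = sq,
                          noise_frac = noise_frac, seed = si + 300L)
    conditions[[i]] <- list(
      label = labels[i],
      truth = ground_truth("condition", si, noise_frac, rg = rg[i],
                           nu = nu[i], tau_i = tau_i[i], H = H[i],
                           rmsd = rmsd[i], tau_nm = tau_nm[i], D0t = D0t,
                           Dr = nm$Dr),
      saxs = saxs, nse_zif = nse_zif, ensemble = reps, nm = nm,
      nse_nm = nse_nm, sq = sq, eta = eta, T = T)
  }
  manifest <- data.frame(label = labels, rg = rg, nu = nu, tau_i = tau_i,
                         H = H, rmsd = rmsd, tau_nm = tau_nm,
                         D0t = vapply(conditions, function(cc) cc$truth$D0t, 0),
                         seed = seed * 1000L + 1:5)
  structure(list(conditions = conditions, manifest = manifest, seed = seed),
            class = "condition_series")
}

#' @export
print.condition_series <- function(x, ...) {
  cat("<condition_series> ground-truth manifest:\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
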