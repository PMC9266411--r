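#' Stokes-Einstein conversions
#'
#' Hydrodynamic radius from a translational diffusion coefficient,
#' \eqn{R_H = k_B T / (6 \pi \eta D)}, and its inverse.
#'
#' @param D translational diffusion \[Angstrom^2/ns\]
#' @param eta solvent viscosity \[mPa s\]
#' @param T temperature \[K\]
#' @return R_H \[Angstrom\]
#' @export
stokes_einstein_rh <- function(D, eta, T) {
  if (any(c(D, eta, T) <= 0)) stop("D, eta and T must be > 0")
  .kB * T * 1e24 / (6 * pi * eta * D)
}

#' @rdname stokes_einstein_rh
#' @param RH hydrodynamic radius \[Angstrom\]
#' @return for `stokes_einstein_d`: D \[Angstrom^2/ns\]
#' @export
stokes_einstein_d <- function(RH, eta, T) {
  if (any(c(RH, eta, T) <= 0)) stop("RH, eta and T must be > 0")
  .stokes_d(RH, eta, T)
}

#' Kirkwood translational diffusion of a bead model
#'
#' Kirkwood double-sum estimate
#' \deqn{D = \frac{k_B T}{6\pi\eta a N} +
#'       \frac{k_B T}{6\pi\eta N^2}\sum_{i \ne j} \langle 1/r_{ij}\rangle}
#' evaluated on one conformation (or, via [ensemble_kirkwood_dt()], averaged
#' over an ensemble).  The Kirkwood value is a pre-averaging upper bound on
#' the rigid-body diffusion coefficient.
#'
#' @param chain a [bead_chain()], or a plain N x 3 coordinate matrix for
#'   non-chain bead models (N >= 2)
#' @param eta viscosity \[mPa s\]
#' @param T temperature \[K\]
#' @param bead_radius hydrodynamic bead radius \[Angstrom\]; 1.9 A for
#'   1-residue beads, 4.5 A for ~8-residue beads
#' @return D0t \[Angstrom^2/ns\]
#' @export
kirkwood_dt <- function(chain, eta, T, bead_radius = 1.9) {
  xyz <- .as_coords(chain)
  N <- nrow(xyz)
  s <- 2 * sum(1 / dist(xyz))
  .mobility_scale(eta, T) * (1 / (6 * pi * bead_radius * N) + s / (6 * pi * N^2))
}

#' @rdname kirkwood_dt
#' @param ens a [bead_ensemble()]; the double sum is population averaged
#'   before inversion, as in the Kirkwood formula
#' @export
ensemble_kirkwood_dt <- function(ens, eta, T, bead_radius = 1.9) {
  stopifnot(inherits(ens, "bead_ensemble"))
  N <- nrow(ens$chains[[1]]$coords)
  s <- sum(ens$weights *
             vapply(ens$chains, function(ch) 2 * sum(1 / dist(ch$coords)), 0))
  .mobility_scale(eta, T) * (1 / (6 * pi * bead_radius * N) + s / (6 * pi * N^2))
}

.as_coords <- function(x) {
  if (inherits(x, "bead_chain")) return(x$coords)
  x <- as.matrix(x)
  if (ncol(x) != 3 || nrow(x) < 2)
    stop("expected a bead_chain or an N x 3 coordinate matrix (N >= 2)")
  unname(x)
}

# Rotne-Prager-Yamakawa pair mobility, reduced units (lengths A, eta = 1).
# Returns the 3Nx3N grand mobility matrix.
.rpy_mobility <- function(xyz, a) {
  N <- nrow(xyz)
  M <- matrix(0, 3 * N, 3 * N)
  self <- diag(3) / (6 * pi * a)
  for (i in seq_len(N)) {
    ii <- 3 * i - 2:0
    M[ii, ii] <- self
    if (i < N) for (j in (i + 1):N) {
      rv <- xyz[j, ] - xyz[i, ]
      r <- sqrt(sum(rv^2))
      P <- outer(rv, rv) / r^2
      Mij <- if (r >= 2 * a) {
        ((1 + 2 * a^2 / (3 * r^2)) * diag(3) + (1 - 2 * a^2 / r^2) * P) / (8 * pi * r)
      } else {                         # overlap branch
        ((1 - 9 * r / (32 * a)) * diag(3) + 3 * r / (32 * a) * P) / (6 * pi * a)
      }
      jj <- 3 * j - 2:0
      M[ii, jj] <- Mij
      M[jj, ii] <- Mij
    }
  }
  M
}

.skew <- function(v)
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)

#' Rigid-body diffusion tensor of a bead model
#'
#' Builds the 3N x 3N Rotne-Prager-Yamakawa mobility supermatrix (overlap
#' branch included), inverts it to the grand friction matrix, reduces to the
#' 6 x 6 rigid-body resistance, and reports translational and rotational
#' diffusion at the center of diffusion.
#'
#' @inheritParams kirkwood_dt
#' @return object of class `hydro_result`: list with `D0t` (trace/3 of the
#'   translational tensor, \[Angstrom^2/ns\]), `Dr` (trace/3 rotational,
#'   \[1/ns\]), `RH` (Stokes-Einstein radius \[Angstrom\]), `tau_r` =
#'   1/(6 Dr) \[ns\], and the full 6x6 tensor `D6`
#' @export
rigid_body_diffusion <- function(chain, eta, T, bead_radius = 1.9) {
  xyz <- .as_coords(chain)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  N <- nrow(xyz)
  M <- .rpy_mobility(xyz, bead_radius)
  Z <- tryCatch(solve(M), error = function(e)
    stop("singular RPY mobility matrix: degenerate bead geometry"))
  d6 <- function(pts) {
    B <- matrix(0, 3 * N, 6)
    for (j in seq_len(N)) {
      jj <- 3 * j - 2:0
      B[jj, 1:3] <- diag(3)
      B[jj, 4:6] <- -.skew(pts[j, ])
    }
    R6 <- crossprod(B, Z %*% B)
    tryCatch(solve(R6), error = function(e)
      stop("singular rigid-body resistance matrix: degenerate (collinear?) geometry"))
  }
  D <- d6(xyz)
  # shift to the center of diffusion (decouples rotation from translation)
  Drr <- D[4:6, 4:6]; Dtr <- D[1:3, 4:6]
  A <- matrix(c(Drr[2, 2] + Drr[3, 3], -Drr[1, 2], -Drr[1, 3],
                -Drr[1, 2], Drr[1, 1] + Drr[3, 3], -Drr[2, 3],
                -Drr[1, 3], -Drr[2, 3], Drr[1, 1] + Drr[2, 2]), 3, 3)
  cvec <- c(Dtr[3, 2] - Dtr[2, 3], Dtr[1, 3] - Dtr[3, 1], Dtr[2, 1] - Dtr[1, 2])
  rod <- tryCatch(solve(A, cvec), error = function(e) c(0, 0, 0))
  D <- d6(sweep(xyz, 2, rod))
  C <- .mobility_scale(eta, T)
  D0t <- C * sum(diag(D[1:3, 1:3])) / 3
  Dr <- C * sum(diag(D[4:6, 4:6])) / 3
  structure(list(D0t = D0t, Dr = Dr,
                 RH = stokes_einstein_rh(D0t, eta, T),
                 tau_r = 1 / (6 * Dr), D6 = C * D,
                 eta = eta, T = T, bead_radius = bead_radius),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf(
    "D0t = %.3f A^2/ns   Dr = %.5f 1/ns   tau_r = %.1f ns   RH = %.2f A\n",
    x$D0t, x$Dr, x$tau_r, x$RH))
  invisible(x)
}

#' Population-weighted hydrodynamics of an ensemble
#'
#' Runs [rigid_body_diffusion()] per chain and averages D0t and Dr linearly
#' in the population weights.
#'
#' @inheritParams kirkwood_dt
#' @param ens a [bead_ensemble()]
#' @return `hydro_result` with weighted-average D0t, Dr (tau_r and RH
#'   derived from the averages)
#' @export
ensemble_hydro <- function(ens, eta, T, bead_radius = 1.9) {
  stopifnot(inherits(ens, "bead_ensemble"))
  hs <- lapply(ens$chains, rigid_body_diffusion, eta = eta, T = T,
               bead_radius = bead_radius)
  D0t <- sum(ens$weights * vapply(hs, `[[`, 0, "D0t"))
  Dr <- sum(ens$weights * vapply(hs, `[[`, 0, "Dr"))
  structure(list(D0t = D0t, Dr = Dr,
                 RH = stokes_einstein_rh(D0t, eta, T),
                 tau_r = 1 / (6 * Dr), D6 = NULL,
                 eta = eta, T = T, bead_radius = bead_radius,
                 per_chain = hs),
            class = "hydro_result")
}

#' Compactness ratio R_H/R_G
#'
#' The ratio R_H/R_G is a standard compactness indicator: sqrt(5/3) = 1.29
#' for a compact globular (uniform-sphere-like) protein and 0.67 for a
#' random-coil-like chain.  Classification picks the nearer extreme, with
#' an `intermediate` band between the midpoints.
#'
#' @param RH hydrodynamic radius \[Angstrom\]
#' @param RG radius of gyration \[Angstrom\]
#' @return list with `ratio` and `classification` in
#'   `c("compact-like", "intermediate", "coil-like")`
#' @export
compactness_ratio <- function(RH, RG) {
  if (RH <= 0 || RG <= 0) stop("RH and RG must be > 0")
  r <- RH / RG
  lo <- 0.67; hi <- sqrt(5 / 3)
  mid_lo <- lo + (hi - lo) / 3
  mid_hi <- hi - (hi - lo) / 3
  cls <- if (r >= mid_hi) "compact-like"
         else if (r <= mid_lo) "coil-like"
         else "intermediate"
  list(ratio = r, classification = cls)
}

#' Kirkwood R_H/R_G ratio of the ideal chain by Monte Carlo
#'
#' Estimates the random-coil compactness ratio with R_H from the Kirkwood
#' double sum \eqn{R_H = N^2 / \sum_{i\ne j}\langle 1/r_{ij}\rangle} and
#' R_G the root-mean-square ensemble radius, over freely jointed ideal
#' chains.  The discrete double sum carries an O(N^-1/2) bias relative to
#' the continuous-chain value, so the estimator samples several chain
#' lengths and extrapolates 1/sqrt(N) -> 0 by default; the long-chain
#' limit is the textbook coil constant (~0.665, commonly quoted as 0.67).
#'
#' @param n_chains Monte-Carlo chains per chain length
#' @param n_beads integer vector of chain lengths; with
#'   `extrapolate = FALSE` only the first is used and its finite-N ratio
#'   returned
#' @param bond bond length \[Angstrom\] (the ratio is scale invariant)
#' @param seed RNG seed
#' @param extrapolate extrapolate the ratio linearly in 1/sqrt(N)
#' @return list with `ratio`, per-length `ratios`, `n_beads`
#' @export
kirkwood_ratio_mc <- function(n_chains = 2000,
                              n_beads = c(64, 128, 256, 512, 1024),
                              bond = 3.8, seed = 1, extrapolate = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  one <- function(N) {
    rg2 <- numeric(n_chains); sinv <- numeric(n_chains)
    for (c in seq_len(n_chains)) {
      u <- matrix(rnorm(3 * (N - 1)), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * bond
      xyz <- rbind(0, apply(u, 2, cumsum))
      xyz <- sweep(xyz, 2, colMeans(xyz))
      rg2[c] <- mean(rowSums(xyz^2))
      sinv[c] <- 2 * sum(1 / dist(xyz))
    }
    (N^2 / mean(sinv)) / sqrt(mean(rg2))
  }
  if (!extrapolate)
    return(list(ratio = one(n_beads[1]), ratios = NULL, n_beads = n_beads[1]))
  ratios <- vapply(n_beads, one, 0)
  x <- 1 / sqrt(n_beads)
  fit <- lm(ratios ~ x)
  list(ratio = unname(coef(fit)[1]), ratios = setNames(ratios, n_beads),
       n_beads = n_beads)
}
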