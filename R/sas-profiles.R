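#' Generalized Gaussian-coil form factor
#'
#' Form factor of a polymer chain with arbitrary scaling exponent nu,
#' a generalization of the classical Debye function,
#' \deqn{P(q) = \frac{1}{\nu U^{1/(2\nu)}}\gamma(1/(2\nu), U)
#'            - \frac{1}{\nu U^{1/\nu}}\gamma(1/\nu, U)}
#' with \eqn{U = (2\nu+1)(2\nu+2) q^2 R_G^2 / 6} and \eqn{\gamma(a,x)} the
#' lower incomplete gamma function.  At nu = 1/2 this reduces exactly to the
#' Debye function \eqn{2(e^{-x}+x-1)/x^2}, \eqn{x = q^2 R_G^2}.  P(0) = 1.
#'
#' The incomplete gamma is evaluated as the regularized form
#' (`pgamma`) times `gamma(a)`; a series expansion takes over for
#' U < 1e-8 so that P(0) = 1 holds exactly.
#'
#' @param q momentum transfer \[1/Angstrom\], >= 0
#' @param rg radius of gyration \[Angstrom\]
#' @param nu scaling exponent, in (0, 1]
#' @param scale forward intensity I(0)
#' @param background constant additive background
#' @return intensities `scale * P(q) + background`
#' @examples
#' q <- seq(0.01, 0.5, 0.01)
#' I <- gauss_coil_formfactor(q, rg = 45, nu = 0.53)
#' @export
gauss_coil_formfactor <- function(q, rg, nu, scale = 1, background = 0) {
  if (!is.finite(nu) || nu <= 0 || nu > 1)
    stop("nu must lie in (0, 1]")
  if (rg <= 0) stop("rg must be > 0")
  U <- (2 * nu + 1) * (2 * nu + 2) * q^2 * rg^2 / 6
  a1 <- 1 / (2 * nu)
  a2 <- 1 / nu
  P <- numeric(length(U))
  small <- U < 1e-8
  # series: P = 1 - U*(1/(nu*(a1+1)) - 1/(nu*(a2+1))) + O(U^2)
  P[small] <- 1 - U[small] * (1 / (nu * (a1 + 1)) - 1 / (nu * (a2 + 1)))
  Ub <- U[!small]
  if (length(Ub)) {
    g1 <- pgamma(Ub, a1) * gamma(a1)
    g2 <- pgamma(Ub, a2) * gamma(a2)
    P[!small] <- g1 / (nu * Ub^a1) - g2 / (nu * Ub^a2)
  }
  scale * P + background
}

#' Fit a generalized Gaussian coil to a scattering curve
#'
#' Weighted Levenberg-Marquardt fit of [gauss_coil_formfactor()] returning
#' (R_G, nu, scale, optionally background) with 1-sigma errors from the
#' covariance and the reduced chi-squared.
#'
#' @param curve a [scattering_curve()]
#' @param rg0,nu0 starting values; `rg0 = NULL` seeds R_G from a free Guinier
#'   estimate on the lowest-q points
#' @param fit_background fit a constant additive background (default TRUE);
#'   if FALSE the background is fixed at 0
#' @param qmin,qmax optional fit range restriction \[1/Angstrom\]
#' @return object of class `gauss_coil_fit` with elements `rg`, `nu`,
#'   `scale`, `background`, `se` (named errors), `cov`, `chi2_red`
#' @export
fit_gauss_coil <- function(curve, rg0 = NULL, nu0 = 0.5,
                           fit_background = TRUE, qmin = NULL, qmax = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  keep <- rep(TRUE, length(curve$q))
  if (!is.null(qmin)) keep <- keep & curve$q >= qmin
  if (!is.null(qmax)) keep <- keep & curve$q <= qmax
  q <- curve$q[keep]; I <- curve$I[keep]; sg <- curve$sigma[keep]
  if (length(q) < 10) stop("need at least 10 points to fit a Gaussian coil")
  if (is.null(rg0)) {
    n0 <- max(5, sum(q <= q[1] * 3))
    sl <- unname(coef(lm(log(pmax(I[1:n0], .Machine$double.xmin)) ~ I(q[1:n0]^2)))[2])
    rg0 <- if (is.finite(sl) && sl < 0) sqrt(-3 * sl) else 30
  }
  par <- c(log_rg = log(rg0), nu = nu0, log_scale = log(max(I[1], 1e-12)))
  if (fit_background) par <- c(par, background = 0)
  resid <- function(p) {
    bg <- if (fit_background) p[["background"]] else 0
    m <- gauss_coil_formfactor(q, exp(p[["log_rg"]]),
                               min(max(p[["nu"]], 0.301), 0.999),
                               exp(p[["log_scale"]]), bg)
    (I - m) / sg
  }
  lo <- c(log(1), 0.301, -Inf, if (fit_background) -Inf)
  hi <- c(log(1e4), 0.999, Inf, if (fit_background) Inf)
  f <- .lm_fit(resid, par, lo, hi, what = "gauss_coil")
  rg <- exp(f$par[["log_rg"]])
  sc <- exp(f$par[["log_scale"]])
  se <- c(rg = unname(f$se["log_rg"]) * rg,      # delta method
          nu = unname(f$se["nu"]),
          scale = unname(f$se["log_scale"]) * sc,
          background = if (fit_background) unname(f$se["background"]) else 0)
  structure(list(rg = rg, nu = f$par[["nu"]], scale = sc,
                 background = if (fit_background) f$par[["background"]] else 0,
                 se = se, cov = f$cov, chi2_red = f$chi2_red,
                 n = length(q)),
            class = "gauss_coil_fit")
}

#' @export
print.gauss_coil_fit <- function(x, ...) {
  cat(sprintf(
    "Generalized Gaussian coil fit (%d pts): RG = %.2f +/- %.2f A,  nu = %.3f +/- %.3f\n",
    x$n, x$rg, x$se["rg"], x$nu, x$se["nu"]))
  cat(sprintf("  I(0) = %.4g, background = %.3g, reduced chi^2 = %.3f\n",
              x$scale, x$background, x$chi2_red))
  invisible(x)
}

#' Guinier analysis with a self-consistent q-range
#'
#' Fits ln I = ln I0 - R^2 q^2 / 3 on the low-q points, iteratively
#' shrinking the upper limit until q_max * R_Guinier <= `qmaxR_limit`
#' (1.1 for expanded chains, 1.3 for compact states).  The returned
#' fixed point satisfies the limit by construction.
#'
#' @param curve a [scattering_curve()]
#' @param qmaxR_limit the Guinier validity product limit (1.1 or 1.3)
#' @param min_points minimum number of points required in the window
#' @return object of class `guinier_result` with `rguinier`, `I0`,
#'   `qmax_used`, `qmaxR`, `se_rg`, `n`
#' @export
guinier_fit <- function(curve, qmaxR_limit = 1.1, min_points = 5) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q; I <- curve$I; sg <- curve$sigma
  pos <- I > 0
  q <- q[pos]; I <- I[pos]; sg <- sg[pos]
  gfit <- function(qmax) {
    s <- q <= qmax
    if (sum(s) < min_points) return(NULL)
    w <- (I[s] / sg[s])^2               # weights for ln I
    f <- lm(log(I[s]) ~ I(q[s]^2), weights = w)
    sl <- coef(f)[2]
    r <- if (sl < 0) sqrt(-3 * sl) else 0
    list(r = unname(r), I0 = exp(unname(coef(f)[1])),
         se_r = if (sl < 0) unname(sqrt(diag(vcov(f)))[2]) * 3 / (2 * unname(r)) else NA_real_,
         n = sum(s), qmax = max(q[s]))
  }
  # initial window: lowest-q fifth of the data
  g <- gfit(q[max(min_points, ceiling(length(q) / 5))])
  if (is.null(g)) stop("insufficient low-q range for Guinier analysis")
  if (g$r <= 0) {
    # flat or rising curve: no measurable radius
    return(structure(list(rguinier = 0, I0 = g$I0, qmax_used = g$qmax,
                          qmaxR = 0, se_rg = NA_real_, n = g$n,
                          flag = "below-resolution"),
                     class = "guinier_result"))
  }
  for (it in 1:50) {
    qlim <- qmaxR_limit / g$r
    g2 <- gfit(qlim)
    if (is.null(g2))
      stop(sprintf(
        "fewer than %d points below q = %.4g 1/A: insufficient Guinier range",
        min_points, qlim))
    if (g2$r <= 0) break
    conv <- abs(g2$r - g$r) / g$r < 1e-6
    g <- g2
    if (conv && g$qmax * g$r <= qmaxR_limit * (1 + 1e-9)) break
  }
  structure(list(rguinier = g$r, I0 = g$I0, qmax_used = g$qmax,
                 qmaxR = g$qmax * g$r, se_rg = g$se_r, n = g$n,
                 flag = if (g$r > 0) "ok" else "below-resolution"),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "Guinier: R = %.2f A (I0 = %.4g), %d pts, qmax*R = %.3f [%s]\n",
    x$rguinier, x$I0, x$n, x$qmaxR, x$flag))
  invisible(x)
}

#' Structure factor from a concentrated/dilute intensity ratio
#'
#' S(q) = (I_conc / c_conc) / (I_dil / c_dil), with the dilute curve
#' interpolated onto the concentrated grid (linear in log I, no
#' extrapolation) and uncertainties by quotient propagation.  Points where
#' the dilute intensity is not positive, or outside the dilute q-support,
#' are dropped with a warning.
#'
#' @param concentrated,dilute [scattering_curve()] objects
#' @param c_conc,c_dil concentrations (same unit, e.g. percent w/v); their
#'   ratio normalizes the division
#' @return object of class `structure_factor_curve` (fields `q`, `S`,
#'   `sigma`)
#' @export
estimate_structure_factor <- function(concentrated, dilute,
                                      c_conc = 1, c_dil = 1) {
  stopifnot(inherits(concentrated, "scattering_curve"),
            inherits(dilute, "scattering_curve"))
  bad_dil <- dilute$I <= 0
  if (any(bad_dil))
    warning(sprintf("%d dilute points with I <= 0 masked", sum(bad_dil)))
  dq <- dilute$q[!bad_dil]; dI <- dilute$I[!bad_dil]
  dsg <- dilute$sigma[!bad_dil]
  inside <- concentrated$q >= min(dq) & concentrated$q <= max(dq)
  if (!all(inside))
    warning(sprintf("%d points outside the dilute q-support dropped",
                    sum(!inside)))
  q <- concentrated$q[inside]
  Ic <- concentrated$I[inside]; sc <- concentrated$sigma[inside]
  Id <- .interp_logy(dq, dI, q)
  # relative error of dilute interpolated linearly as well
  rel_d <- approx(dq, dsg / dI, xout = q, rule = 1)$y
  S <- (Ic / c_conc) / (Id / c_dil)
  sigma <- abs(S) * sqrt((sc / Ic)^2 + rel_d^2)
  structure(list(q = q, S = S, sigma = sigma),
            class = "structure_factor_curve")
}

#' @export
print.structure_factor_curve <- function(x, ...) {
  cat(sprintf("<structure_factor_curve> %d points, S in [%.3g, %.3g]\n",
              length(x$q), min(x$S), max(x$S)))
  invisible(x)
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic Percus-Yevick solution for non-charged hard spheres with
#' excluded-volume interactions.  Satisfies the compressibility limit
#' \eqn{S(0) = (1-\phi)^4/(1+2\phi)^2} and S -> 1 as q -> infinity or
#' phi -> 0.
#'
#' @param q momentum transfer \[1/Angstrom\]
#' @param r_hs effective hard-sphere radius \[Angstrom\]
#' @param phi volume fraction, 0 <= phi < 0.74
#' @return S(q) values
#' @export
hard_sphere_sq <- function(q, r_hs, phi) {
  if (phi < 0 || phi >= 0.74) stop("phi must lie in [0, 0.74)")
  if (r_hs <= 0) stop("r_hs must be > 0")
  if (phi == 0) return(rep(1, length(q)))
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  ga <- phi * al / 2
  A <- 2 * r_hs * q
  # per-term G(A)/A; series branch avoids catastrophic cancellation
  f1 <- f2 <- f3 <- numeric(length(A))
  s <- A < 0.05
  As <- A[s]
  f1[s] <- 1 / 3 - As^2 / 30
  f2[s] <- 1 / 4 - As^2 / 36
  f3[s] <- 1 / 6 - As^2 / 48
  Ab <- A[!s]
  if (length(Ab)) {
    f1[!s] <- (sin(Ab) - Ab * cos(Ab)) / Ab^3
    f2[!s] <- (2 * Ab * sin(Ab) + (2 - Ab^2) * cos(Ab) - 2) / Ab^4
    f3[!s] <- (-Ab^4 * cos(Ab) +
               4 * ((3 * Ab^2 - 6) * cos(Ab) + (Ab^3 - 6 * Ab) * sin(Ab) + 6)) / Ab^6
  }
  G_over_A <- al * f1 + be * f2 + ga * f3
  1 / (1 + 24 * phi * G_over_A)
}

#' Fit a Percus-Yevick hard-sphere model to a structure factor
#'
#' @param sq a `structure_factor_curve` from [estimate_structure_factor()]
#'   (or a list with fields `q`, `S`, `sigma`)
#' @param r0,phi0 starting values
#' @return list with `r_hs`, `phi`, `se`, `chi2_red`
#' @export
fit_hard_sphere <- function(sq, r0 = 30, phi0 = 0.05) {
  q <- sq$q; S <- sq$S; sg <- sq$sigma
  par <- c(log_r = log(r0), phi = phi0)
  resid <- function(p)
    (S - hard_sphere_sq(q, exp(p[["log_r"]]),
                        min(max(p[["phi"]], 0), 0.7399))) / sg
  f <- .lm_fit(resid, par, c(log(0.1), 0), c(log(1e4), 0.7399),
               what = "hard_sphere")
  r_hs <- exp(f$par[["log_r"]])
  list(r_hs = r_hs, phi = f$par[["phi"]],
       se = c(r_hs = unname(f$se["log_r"]) * r_hs, phi = unname(f$se["phi"])),
       chi2_red = f$chi2_red)
}

#' Reciprocal-space marker of the stiff segment
#'
#' The persistence length l_p of a semiflexible chain appears in reciprocal
#' space at q* = 1.91 / l_p.
#'
#' @param lp persistence length \[Angstrom\], > 0
#' @return q* \[1/Angstrom\]
#' @export
stiff_segment_q <- function(lp) {
  if (any(lp <= 0)) stop("persistence length must be > 0")
  1.91 / lp
}
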