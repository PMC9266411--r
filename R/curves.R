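#' Scattering curve container
#'
#' A (q, I, sigma) small-angle scattering profile, the unit of all SAS input
#' and output.  The grid must be strictly increasing with q > 0 and positive
#' uncertainties.
#'
#' @param q momentum transfer grid \[1/Angstrom\], strictly increasing
#' @param I intensities (arbitrary units)
#' @param sigma 1-sigma uncertainties, same length as `q`
#' @param meta free-form list of labels (concentration, probe, condition)
#' @return an object of class `scattering_curve`: a list with elements
#'   `q`, `I`, `sigma` and `meta`
#' @seealso [read_sas()], [kratky_transform()]
#' @export
scattering_curve <- function(q, I, sigma, meta = list()) {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal length")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  structure(list(q = q, I = I, sigma = sigma, meta = meta),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  if (length(x$meta)) {
    lab <- paste(names(x$meta), vapply(x$meta, function(v)
      paste(format(v), collapse = ","), ""), sep = "=", collapse = "  ")
    cat(" ", lab, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  data.frame(q = x$q, I = x$I, sigma = x$sigma)
}

#' Kratky transform of a scattering curve
#'
#' Returns the pairs (q, q^2 I(q)) used to visualize deviations from
#' Gaussian-coil behavior; Gaussian coils plateau, expanded chains rise.
#' Uncertainties are propagated as q^2 sigma.
#'
#' @param curve a [scattering_curve()]
#' @return data.frame with columns `q`, `qsqI`, `sigma`
#' @export
kratky_transform <- function(curve) {
  stopifnot(inherits(curve, "scattering_curve"))
  data.frame(q = curve$q, qsqI = curve$q^2 * curve$I,
             sigma = curve$q^2 * curve$sigma)
}

#' Neutron spin-echo dataset
#'
#' Normalized intermediate scattering function points I(q,t)/I(q,0) grouped
#' by momentum transfer, with condition metadata used by the dynamic models.
#'
#' @param q momentum transfer \[1/Angstrom\] per point
#' @param t Fourier time \[ns\] per point, >= 0
#' @param fnorm normalized ISF values I(q,t)/I(q,0)
#' @param sigma 1-sigma uncertainties
#' @param T sample temperature \[K\]
#' @param eta solvent viscosity \[mPa s\]
#' @param meta free-form list (protein concentration, condition label, ...)
#' @return object of class `nse_dataset` wrapping a data.frame with columns
#'   `q`, `t`, `fnorm`, `sigma`
#' @export
nse_dataset <- function(q, t, fnorm, sigma, T = 295, eta = 1.1, meta = list()) {
  d <- data.frame(q = as.numeric(q), t = as.numeric(t),
                  fnorm = as.numeric(fnorm), sigma = as.numeric(sigma))
  if (any(d$t < 0)) stop("t must be >= 0")
  if (any(d$sigma <= 0)) stop("sigma must be > 0")
  if (anyDuplicated(d[c("q", "t")])) stop("duplicate (q, t) pairs")
  d <- d[order(d$q, d$t), ]
  rownames(d) <- NULL
  structure(list(data = d, T = T, eta = eta, meta = meta),
            class = "nse_dataset")
}

#' @export
print.nse_dataset <- function(x, ...) {
  qs <- unique(x$data$q)
  cat(sprintf(
    "<nse_dataset> %d points at %d q-values (%.3g..%.3g 1/A), t up to %.3g ns\n",
    nrow(x$data), length(qs), min(qs), max(qs), max(x$data$t)))
  cat(sprintf("  T = %g K, eta = %g mPa s\n", x$T, x$eta))
  invisible(x)
}

#' @export
as.data.frame.nse_dataset <- function(x, ...) x$data

# shared interpolation dialect: linear in log(y) on x; never extrapolates
.interp_logy <- function(x, y, xout) {
  if (any(y <= 0)) stop("log-interpolation requires positive values")
  res <- approx(x, log(y), xout = xout, rule = 1)$y
  exp(res)
}
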