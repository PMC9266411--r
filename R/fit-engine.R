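# Shared Levenberg-Marquardt wrapper.
#
# residfun(par) must return weighted residuals (data - model)/sigma.
# Reports 1-sigma errors from the scaled covariance (J'J)^-1 * chi2_red and
# the reduced chi^2 = sum(res^2)/(n - k), the convention used throughout.
.lm_fit <- function(residfun, par, lower = NULL, upper = NULL,
                    maxit = 200, what = "model") {
  if (is.null(lower)) lower <- rep(-Inf, length(par))
  if (is.null(upper)) upper <- rep(Inf, length(par))
  fit <- minpack.lm::nls.lm(
    par = par, fn = residfun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxit))
  if (fit$info == 0 || fit$info == 9)
    stop(sprintf("%s fit did not converge (nls.lm info %d); last parameters: %s",
                 what, fit$info,
                 paste(names(par), signif(unlist(fit$par), 4),
                       sep = "=", collapse = ", ")))
  res <- fit$fvec
  ndf <- length(res) - length(par)
  chi2_red <- sum(res^2) / max(ndf, 1)
  covm <- tryCatch(chi2_red * solve(fit$hessian / 2),
                   error = function(e) matrix(NA_real_, length(par), length(par)))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(par)
  list(par = unlist(fit$par), se = se, cov = covm,
       chi2_red = chi2_red, ndf = ndf, niter = fit$niter, info = fit$info)
}
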