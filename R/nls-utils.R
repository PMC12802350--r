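# Shared nonlinear least-squares machinery.
#
# All fitters optimize log-transformed positive parameters with
# Levenberg-Marquardt (minpack.lm::nls.lm) under box bounds on the log
# scale, then map standard errors back to the natural scale by the delta
# method (d exp(t)/dt = exp(t), so se_nat = value * se_log).

# central-difference Jacobian of a residual function
num_jacobian <- function(fn, par, eps = 1e-7) {
  r0 <- fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

# least-squares fit on log-scale parameters; returns natural-scale
# estimates, delta-method SEs, rss and convergence info
fit_log_ls <- function(resid_fn, start, lower = NULL, upper = NULL,
                       maxiter = 200) {
  nm <- names(start)
  theta0 <- log(start)
  if (is.null(lower)) lower <- rep(log(1e-9), length(start))
  if (is.null(upper)) upper <- rep(log(1e9), length(start))
  fn <- function(theta) resid_fn(stats::setNames(exp(theta), nm))
  out <- minpack.lm::nls.lm(
    par = theta0, fn = fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-14, ptol = 1e-14)
  )
  theta <- out$par
  est <- stats::setNames(exp(theta), nm)
  res <- fn(theta)
  rss <- sum(res^2)
  n <- length(res)
  k <- length(theta)
  # SEs from the Jacobian at the optimum; singular information -> NA
  se <- stats::setNames(rep(NA_real_, k), nm)
  if (n > k) {
    J <- num_jacobian(fn, theta)
    sigma2 <- rss / (n - k)
    cv <- tryCatch(chol2inv(chol(crossprod(J))) * sigma2,
                   error = function(e) NULL)
    if (!is.null(cv)) se <- est * sqrt(pmax(diag(cv), 0))
  }
  converged <- out$info %in% 1:4
  at_lower <- abs(theta - lower) < 1e-8
  list(estimate = est, se = se, rss = rss, n = n, k = k,
       residuals = -res, converged = converged, info = out$info,
       message = out$message, at_lower_bound = stats::setNames(at_lower, nm),
       niter = out$niter)
}
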