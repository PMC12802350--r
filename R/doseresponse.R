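#' Three-parameter log-logistic dose-response function
#'
#' The decreasing log-logistic with lower asymptote fixed at zero,
#' \deqn{f(x) = \frac{d}{1 + \exp\{b(\ln x - \ln e)\}},}
#' where `d` is the zero-dose response, `e` the inflection dose (the IC50)
#' and `b > 0` the slope. Dose zero is handled by the `b > 0` limit,
#' `f(0) = d`, so zero-dose controls inform the upper asymptote instead of
#' being dropped.
#'
#' @param dose dose(s), µM; non-negative.
#' @param b slope, dimensionless, positive.
#' @param d upper asymptote, response units.
#' @param e inflection dose (IC50), µM.
#' @return Response value(s).
#' @examples
#' loglogistic3(0.5, b = 1.5, d = 10, e = 0.5)  # d/2 at the inflection
#' @export
loglogistic3 <- function(dose, b, d, e) {
  stopifnot(all(dose >= 0), b > 0, d > 0, e > 0)
  out <- numeric(length(dose))
  z <- dose > 0
  out[!z] <- d
  out[z] <- d / (1 + exp(b * (log(dose[z]) - log(e))))
  out
}

#' Fit a three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of [loglogistic3()] to responses at increasing
#' inhibitor doses; the fitted inflection `e` is reported as the IC50 at
#' that substrate level. Deterministic initialization: `d` starts at the
#' maximum response, `e` at the dose bracketing half-maximum by linear
#' interpolation, `b` at 1. Responses may be raw rates or ratios
#' normalized to the uninhibited rate; for ratio data the upper asymptote
#' can be pinned with `fix_d = 1` (reported with zero standard error).
#'
#' Responses that rise with dose beyond what noise explains (response at
#' the top dose exceeding the zero/low-dose response) are flagged with a
#' warning, since a decreasing curve is then mis-specified.
#'
#' @param dose inhibitor doses, µM; at least 4 points with at least 3
#'   distinct nonzero doses.
#' @param response responses, same length as `dose`.
#' @param fix_d optional value at which to fix the upper asymptote.
#' @return An object of class `"ll3_fit"`: list with `b`, `d`, `e` (and
#'   `ic50`, an alias of `e`), `se` (named vector), `rss`, `n`,
#'   `converged`, `fitted`, `residuals`, `data`.
#' @examples
#' x <- c(0, 0.05, 0.1, 0.25, 0.5, 1, 2, 4)
#' y <- loglogistic3(x, b = 1.5, d = 10, e = 0.5)
#' fit <- fit_loglogistic3(x, y)
#' fit$ic50
#' @export
fit_loglogistic3 <- function(dose, response, fix_d = NULL) {
  stopifnot(length(dose) == length(response), all(is.finite(response)))
  if (length(dose) < 4L) stop("need at least 4 dose-response points")
  if (any(dose < 0)) stop("doses must be non-negative")
  if (length(unique(dose[dose > 0])) < 3L) {
    stop("need at least 3 distinct nonzero doses")
  }
  ord <- order(dose)
  x <- dose[ord]; y <- response[ord]
  top <- mean(y[x == min(x)])
  if (mean(y[x == max(x)]) > top + 0.05 * abs(top)) {
    warning("responses increase with dose; decreasing log-logistic may be ",
            "mis-specified")
  }
  d0 <- if (is.null(fix_d)) max(y) else fix_d
  # dose bracketing half-max, by interpolation on the sorted curve
  half <- d0 / 2
  below <- which(y <= half)
  e0 <- if (length(below) && min(below) > 1L) {
    i <- min(below)
    x0 <- max(x[i - 1], min(x[x > 0]))
    exp(stats::approx(c(y[i - 1], y[i]), log(c(x0, x[i])), xout = half,
                      ties = "ordered")$y)
  } else stats::median(x[x > 0])
  if (!is.finite(e0) || e0 <= 0) e0 <- stats::median(x[x > 0])

  free <- c("b", if (is.null(fix_d)) "d", "e")
  start <- c(b = 1, d = d0, e = e0)
  resid_fn <- function(p) {
    full <- c(as.list(p), if (!is.null(fix_d)) list(d = fix_d))
    loglogistic3(x, full$b, full$d, full$e) - y
  }
  fit <- fit_log_ls(resid_fn, start[free])
  if (!fit$converged) {
    stop("log-logistic fit did not converge: ", fit$message)
  }
  est <- as.list(fit$estimate)
  se <- c(b = unname(fit$se[["b"]]),
          d = if (is.null(fix_d)) unname(fit$se[["d"]]) else 0,
          e = unname(fit$se[["e"]]))
  structure(list(
    b = est$b, d = est$d %||% fix_d, e = est$e, ic50 = est$e,
    se = se, rss = fit$rss, n = fit$n,
    fixed_d = !is.null(fix_d),
    converged = fit$converged,
    residuals = fit$residuals,
    fitted = y - fit$residuals,
    data = data.frame(dose = x, response = y)
  ), class = "ll3_fit")
}

#' @export
coef.ll3_fit <- function(object, ...) {
  c(b = object$b, d = object$d, e = object$e)
}

#' @export
predict.ll3_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose else {
    if (is.data.frame(newdata)) newdata$dose else newdata
  }
  loglogistic3(x, object$b, object$d, object$e)
}

#' @export
residuals.ll3_fit <- function(object, ...) object$residuals

#' @export
print.ll3_fit <- function(x, ...) {
  cat("Three-parameter log-logistic fit\n")
  cat(sprintf("  b (slope) = %.4g (+/- %.3g)\n", x$b, x$se[["b"]]))
  cat(sprintf("  d (top)   = %.4g (+/- %.3g)%s\n", x$d, x$se[["d"]],
              if (x$fixed_d) " (fixed)" else ""))
  cat(sprintf("  e = IC50  = %.4g (+/- %.3g) uM\n", x$e, x$se[["e"]]))
  cat(sprintf("  RSS = %.4g on %d points\n", x$rss, x$n))
  invisible(x)
}

#' @export
plot.ll3_fit <- function(x, ...) {
  d <- x$data
  xp <- d$dose
  xg <- exp(seq(log(max(min(xp[xp > 0]) / 4, 1e-6)), log(max(xp) * 2),
                length.out = 100))
  plot(pmax(xp, min(xp[xp > 0]) / 4), d$response, log = "x",
       xlab = "[I] (uM)", ylab = "response",
       main = "log-logistic dose-response", ...)
  graphics::lines(xg, predict(x, xg), col = 2)
  graphics::abline(v = x$e, lty = 2, col = "grey40")
  invisible(x)
}
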