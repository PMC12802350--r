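#' Apparent inhibition constant for a given inhibition mode
#'
#' The substrate dependence of the apparent inhibition constant
#' \eqn{K_i^{app}} encodes the inhibition mode:
#' \describe{
#'   \item{competitive}{\eqn{K_i^{app} = K_i (1 + S/K_m)}}
#'   \item{noncompetitive (mixed)}{\eqn{K_i^{app} = (S + K_m) /
#'     (K_m/K_i + S/(\alpha K_i))}, i.e.
#'     \eqn{\alpha K_i (S + K_m)/(\alpha K_m + S)}}
#'   \item{uncompetitive}{\eqn{K_i^{app} = K_i (1 + K_m/S)}}
#' }
#' With \eqn{\alpha = 1} the noncompetitive form reduces to \eqn{K_i}
#' independently of substrate (pure noncompetitive inhibition); mixed
#' inhibition (\eqn{\alpha \neq 1}) is bounded between
#' \eqn{K_i \min(1,\alpha)} and \eqn{K_i \max(1,\alpha)}.
#'
#' @param mode one of `"competitive"`, `"noncompetitive"`,
#'   `"uncompetitive"`.
#' @param S substrate concentration(s), µM. Must be strictly positive for
#'   the uncompetitive mode.
#' @param Km Michaelis constant, µM.
#' @param Ki true inhibition constant, µM.
#' @param alpha mixed-inhibition factor (noncompetitive mode only).
#' @return Apparent inhibition constant(s) in µM, same length as `S`.
#' @examples
#' ki_app("competitive", S = 100, Km = 100, Ki = 0.3)  # 2 * Ki
#' ki_app("noncompetitive", S = 50, Km = 100, Ki = 0.3, alpha = 1)  # Ki
#' @export
ki_app <- function(mode, S, Km, Ki, alpha = NULL) {
  mode <- match.arg(mode, c("competitive", "noncompetitive", "uncompetitive"))
  stopifnot(is.numeric(S), all(is.finite(S)), all(S >= 0),
            is.numeric(Km), Km > 0, is.numeric(Ki), Ki > 0)
  switch(mode,
    competitive = Ki * (1 + S / Km),
    noncompetitive = {
      if (is.null(alpha) || !is.numeric(alpha) || alpha <= 0) {
        stop("noncompetitive mode requires a positive 'alpha'")
      }
      (S + Km) / (Km / Ki + S / (alpha * Ki))
    },
    uncompetitive = {
      if (any(S <= 0)) {
        stop("uncompetitive Ki_app is undefined at S = 0")
      }
      Ki * (1 + Km / S)
    }
  )
}

#' Morrison fractional velocity for tight-binding inhibition
#'
#' Fractional residual velocity \eqn{v_i/v_0} from Morrison's closed-form
#' solution of the enzyme-inhibitor binding quadratic, valid when inhibitor
#' depletion by binding cannot be neglected (tight binding):
#' \deqn{\frac{v_i}{v_0} = 1 - \frac{([E]+[I]+K_i^{app}) -
#'   \sqrt{([E]+[I]+K_i^{app})^2 - 4[E][I]}}{2[E]}}
#'
#' The square-root discriminant is clamped at zero against floating-point
#' underflow and the result is clipped to \eqn{[0, 1]}. As
#' \eqn{[E] \to 0} the expression tends to the classical (non-depleting)
#' isotherm \eqn{K_i^{app}/(K_i^{app} + [I])}.
#'
#' @param E active enzyme concentration, µM; strictly positive.
#' @param I total inhibitor concentration(s), µM; non-negative.
#' @param Ki_app apparent inhibition constant(s), µM; positive.
#' @return Fractional velocity in \[0, 1\], vectorized over `I`/`Ki_app`.
#' @examples
#' morrison_ratio(E = 0.2, I = 0, Ki_app = 0.3)    # 1: no inhibitor
#' morrison_ratio(E = 0.1, I = 0.1, Ki_app = 0.3)  # ~0.791
#' @export
morrison_ratio <- function(E, I, Ki_app) {
  if (!is.numeric(E) || any(!is.finite(E)) || any(E <= 0)) {
    stop("'E' must be strictly positive; use the classical limit ",
         "Ki_app/(Ki_app + I) for vanishing enzyme")
  }
  stopifnot(is.numeric(I), all(I >= 0), is.numeric(Ki_app), all(Ki_app > 0))
  b <- E + I + Ki_app
  disc <- pmax(b^2 - 4 * E * I, 0)
  r <- 1 - (b - sqrt(disc)) / (2 * E)
  pmin(pmax(r, 0), 1)
}

#' Predicted inhibited reaction rate on the (S, I) grid
#'
#' The global tight-binding velocity model: the uninhibited
#' Michaelis-Menten rate at the same substrate concentration, scaled by the
#' Morrison fractional velocity,
#' \deqn{v_i(S, I) = \frac{V_{max} S}{K_m + S} \cdot
#'   \mathrm{morrison\_ratio}([E], I, K_i^{app}(S))}
#'
#' @param S substrate concentration(s), µM.
#' @param I inhibitor concentration(s), µM (recycled against `S`).
#' @param params a [tb_params] object (or compatible named list).
#' @param mode inhibition mode, see [ki_app()].
#' @return Predicted rate(s) in nmol/min.
#' @examples
#' p <- gc7_reference_params()
#' predict_rate(S = 100, I = 0.5, p, "noncompetitive")
#' @export
predict_rate <- function(S, I, params, mode) {
  params <- as_tb_params(params)
  n <- max(length(S), length(I))
  S <- rep_len(S, n)
  I <- rep_len(I, n)
  v0 <- mm_velocity(S, Km = params$Km, Vmax = params$Vmax)
  ka <- ki_app(mode, S, Km = params$Km, Ki = params$Ki, alpha = params$alpha)
  v0 * morrison_ratio(params$E, I, ka)
}

#' Tight-binding IC50 at a given substrate concentration
#'
#' The inhibitor concentration at which the Morrison fractional velocity
#' equals one half. For the tight-binding isotherm this has the closed form
#' \deqn{IC_{50} = K_i^{app}(S) + [E]/2,} which reduces to the classical
#' \eqn{IC_{50} = K_i^{app}} as \eqn{[E] \to 0}.
#'
#' @inheritParams predict_rate
#' @return IC50 value(s) in µM, one per element of `S`.
#' @examples
#' ic50_tight_binding(gc7_reference_params(), "noncompetitive", S = 173.8)
#' @export
ic50_tight_binding <- function(params, mode, S) {
  params <- as_tb_params(params)
  ki_app(mode, S, Km = params$Km, Ki = params$Ki, alpha = params$alpha) +
    params$E / 2
}
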