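#' Wright omega function (real line, overflow-free)
#'
#' Computes \eqn{\omega(z)}, the unique positive solution of
#' \eqn{\omega + \log\omega = z} for real \eqn{z}. On the real line
#' \eqn{\omega(z) = W_0(e^z)}, but \eqn{\omega} is evaluated directly from
#' \eqn{z} so that \eqn{e^z} is never materialized: arguments such as
#' \eqn{z = 10^4}, which arise in the Lambert-W closed forms for small
#' \code{a50} or large doses, pose no overflow risk.
#'
#' The evaluation uses a starting guess chosen by the size of \eqn{z}
#' (\eqn{e^z} for very negative \eqn{z}, \eqn{z - \log z} for large \eqn{z},
#' a rational blend in between) refined by Newton iteration on
#' \eqn{f(\omega) = \omega + \log\omega - z}, which is smooth and strictly
#' increasing for \eqn{\omega > 0}, so convergence is monotone and
#' quadratic. Iteration stops at machine-precision residuals.
#'
#' @param z Finite real number(s).
#' @return \eqn{\omega(z)}, same length as \code{z}; always \code{> 0}
#'   (underflowing to 0 for \eqn{z} below about \eqn{-745}).
#' @examples
#' wright_omega(1)        # exactly 1
#' wright_omega(0)        # the omega constant 0.5671...
#' wright_omega(1000)     # no overflow: about 993.1
#' @export
wright_omega <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("z must be finite real", call. = FALSE)
  vapply(z, wright_omega_scalar, numeric(1))
}

wright_omega_scalar <- function(z) {
  # initial guess: omega ~ e^z for z << 0; omega ~ z - log z for z >> 1
  if (z < -1) {
    w <- exp(z)                      # omega = e^z(1 - e^z + ...) for z -> -inf
    if (w == 0) return(0)            # underflow: omega < realmin
  } else if (z > 2) {
    w <- z - log(z)
  } else {
    w <- max(0.5 * (1 + z), 0.1)     # crude but inside the convergence basin
  }
  for (i in 1:100) {
    f <- w + log(w) - z
    dw <- f * w / (1 + w)            # Newton step on w + log(w) - z
    wn <- w - dw
    if (wn <= 0) wn <- w / 2         # safeguard: stay on the positive axis
    if (abs(wn - w) <= 4 * .Machine$double.eps * abs(wn)) return(wn)
    w <- wn
  }
  w
}

#' Principal-branch Lambert W function
#'
#' Computes \eqn{W_0(x)}, the inverse of \eqn{f(w) = w e^w}, for
#' \eqn{x \ge 0} (the only regime the absorption closed forms generate:
#' every W argument arising from positive amounts is non-negative, where
#' the principal branch is single-valued and non-negative). Evaluated as
#' \eqn{\omega(\log x)} via [wright_omega()].
#'
#' @param x Non-negative real number(s).
#' @return \eqn{w \ge 0} with \eqn{w e^w = x}.
#' @examples
#' lambert_w0(0)          # 0
#' lambert_w0(exp(1))     # 1
#' @export
lambert_w0 <- function(x) {
  if (!is.numeric(x) || any(is.na(x)))
    stop("x must be numeric and non-missing", call. = FALSE)
  if (any(x < 0))
    stop("lambert_w0 requires x >= 0 (negative arguments never arise ",
         "from valid absorption parameters)", call. = FALSE)
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- wright_omega(log(x[pos]))
  out
}
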