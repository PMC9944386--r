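#' Left-hand side of the general integrated relation (case A)
#'
#' Separable integration of the generalized model with \code{gamma1 != 1}
#' and \code{gamma2 - gamma1 + 1 != 0} yields the implicit relation
#' \deqn{\frac{A^{\gamma_2-\gamma_1+1}}{\gamma_2-\gamma_1+1}
#'   + \frac{A_{50}^{\gamma_2}}{1-\gamma_1} A^{1-\gamma_1} = Q_a(t).}
#' This function evaluates the left-hand side. Its derivative in \code{a}
#' is \eqn{(a^{\gamma_2} + a_{50}^{\gamma_2})/a^{\gamma_1} > 0}, so it is
#' strictly increasing: the implicit relation pins down a unique amount.
#'
#' @param params An \code{absorption_params} bundle with \code{gamma1 != 1}
#'   and \code{gamma2 - gamma1 + 1 != 0}.
#' @param a Amount(s), each \code{> 0}.
#' @return Value(s) of the integrated left-hand side.
#' @export
lhs_case_a <- function(params, a) {
  params <- as_absorption_params(params)
  g1 <- params$gamma1; g2 <- params$gamma2
  e1 <- g2 - g1 + 1
  e2 <- 1 - g1
  if (e2 == 0 || e1 == 0)
    stop("lhs_case_a undefined for gamma1 = 1 or gamma2 - gamma1 = -1 ",
         "(use the case B/C/D forms)", call. = FALSE)
  if (any(a <= 0)) stop("a must be > 0", call. = FALSE)
  a^e1 / e1 + params$a50^g2 * a^e2 / e2
}

#' Integrated right-hand constant Q_a
#'
#' The time-dependent constant of the case-A implicit relation:
#' \code{q_a(params, t) = lhs_case_a(params, a0) - k_a_max * t}.
#'
#' @param params As in [lhs_case_a()], with \code{a0 > 0}.
#' @param t Time(s), each \code{>= 0}.
#' @return Value(s) of the constant at \code{t}.
#' @export
q_a <- function(params, t) {
  params <- as_absorption_params(params)
  check_times(t)
  if (params$a0 <= 0) stop("q_a requires a0 > 0", call. = FALSE)
  lhs_case_a(params, params$a0) - params$k_a_max * t
}

#' Left-hand side of the integrated Hill relation
#'
#' For Hill kinetics with exponent \code{gamma != 1} the integrated
#' relation is
#' \deqn{A + \frac{1}{1-\gamma}\frac{A_{50}^\gamma}{A^{\gamma-1}}
#'   = A_0 + \frac{1}{1-\gamma}\frac{A_{50}^\gamma}{A_0^{\gamma-1}}
#'   - k_{a,max} t,}
#' the \code{gamma1 = gamma2 = gamma} diagonal of [lhs_case_a()].
#'
#' @param params A \code{hill_params} object with \code{gamma != 1}.
#' @param a Amount(s), each \code{> 0}.
#' @return Value(s) of the integrated left-hand side.
#' @export
hill_lhs <- function(params, a) {
  stopifnot(inherits(params, "hill_params"))
  if (params$gamma == 1)
    stop("hill_lhs undefined for gamma = 1; use michaelis_menten_amount()",
         call. = FALSE)
  if (any(a <= 0)) stop("a must be > 0", call. = FALSE)
  a + params$a50^params$gamma * a^(1 - params$gamma) / (1 - params$gamma)
}

# Integrated LHS valid for every case, chosen by the exponent regime.
# The log-branch cases use the convention lhs(a0) - k_a_max * t for the
# right-hand constant, so the case-C branch carries a factor 2 relative
# to a bare log.
implicit_lhs <- function(params, a, tol = 1e-12) {
  g1 <- params$gamma1; g2 <- params$gamma2
  a50g2 <- params$a50^g2
  if (abs(g1 - 1) <= tol) {
    if (abs(g2) <= tol) return(2 * log(a))              # case C
    return(a^g2 / g2 + a50g2 * log(a))                  # case B
  }
  if (abs(g2 - g1 + 1) <= tol && g2 > tol)
    return(log(a) - a50g2 / g2 * a^(-g2))               # case D
  e1 <- g2 - g1 + 1
  e2 <- 1 - g1
  a^e1 / e1 + a50g2 * a^e2 / e2                         # case A / power law
}

# TRUE when lhs has a finite limit as a -> 0+, i.e. absorption completes
# in finite time. Requires both exponents positive: 1 - gamma1 > 0 and
# gamma2 - gamma1 + 1 > 0 (the latter is automatic when gamma2 >= 0 and
# gamma1 < 1). The limit itself is then 0.
has_finite_zero_limit <- function(params, tol = 1e-12) {
  g1 <- params$gamma1; g2 <- params$gamma2
  (1 - g1) > tol && (g2 - g1 + 1) > tol
}

#' Time at which absorption completes, if finite
#'
#' Absorption ends in finite time exactly when the integrated left-hand
#' side has a finite limit as the amount approaches zero, which for
#' \code{gamma2 >= 0} happens iff \code{gamma1 < 1}: the end time is then
#' \code{t_end = lhs(a0) / k_a_max} (the zero-limit of the left-hand side
#' is 0). Any \code{gamma1 >= 1} produces a diverging logarithmic or
#' negative-power term, so the amount only decays asymptotically and the
#' end time is infinite.
#'
#' @param params An \code{absorption_params} bundle.
#' @return The finite end time, or \code{Inf}.
#' @examples
#' absorption_end_time(absorption_params(1, 1, 0.5, 0, 100))  # 40
#' absorption_end_time(absorption_params(1, 1, 1, 1, 100))    # Inf
#' @export
absorption_end_time <- function(params) {
  params <- as_absorption_params(params)
  if (params$a0 == 0) return(0)
  if (!has_finite_zero_limit(params)) return(Inf)
  implicit_lhs(params, params$a0) / params$k_a_max
}

#' Solve the implicit amount-time relation numerically
#'
#' Inverts \code{lhs(A) = lhs(a0) - k_a_max * t} for \code{A} at a single
#' time by bracketed root-finding on \code{(0, a0]}. Because the
#' integrated left-hand side is strictly increasing in \code{A} for every
#' exponent regime, the bracket always contains exactly one root and
#' convergence is guaranteed; Brent's method (bisection safeguarded by
#' superlinear interpolation, as in [stats::uniroot()]) refines it. This
#' covers the general regime with no closed form (\code{CASE_A_IMPLICIT},
#' including Hill kinetics with \code{gamma != 1}) and doubles as an
#' independent route to every closed-form case.
#'
#' When the left-hand side has a finite zero-limit (\code{gamma1 < 1}) and
#' the requested time lies at or beyond the finite absorption end time,
#' the amount is exactly 0 and \code{hit_zero} is set.
#'
#' @param params An \code{absorption_params} bundle.
#' @param t A single time, \code{>= 0}.
#' @param tol_rel Relative convergence tolerance on the amount
#'   (default \code{1e-12}).
#' @param tol_abs Absolute tolerance (default \code{1e-15 * a0}).
#' @param max_iter Maximum root-finder iterations (default 200).
#' @return An \code{implicit_solve_report}: list with \code{amount},
#'   \code{iterations}, \code{bracket_width}, \code{hit_zero}.
#' @examples
#' p <- absorption_params(k_a_max = 1, a50 = 1, gamma1 = 2, gamma2 = 3,
#'                        a0 = 2)
#' solve_amount_implicit(p, t = 1)$amount
#' @export
solve_amount_implicit <- function(params, t, tol_rel = 1e-12,
                                  tol_abs = NULL, max_iter = 200L) {
  params <- as_absorption_params(params)
  stopifnot(length(t) == 1L)
  check_times(t)
  a0 <- params$a0
  if (is.null(tol_abs)) tol_abs <- 1e-15 * max(a0, 1)
  report <- function(amount, iterations, bracket_width, hit_zero)
    structure(list(amount = amount, iterations = iterations,
                   bracket_width = bracket_width, hit_zero = hit_zero),
              class = "implicit_solve_report")
  if (a0 == 0) return(report(0, 0L, 0, TRUE))
  q_t <- implicit_lhs(params, a0) - params$k_a_max * t
  if (t == 0) return(report(a0, 0L, 0, FALSE))
  if (has_finite_zero_limit(params) && q_t <= 0)
    return(report(0, 0L, 0, TRUE))

  f <- function(a) implicit_lhs(params, a) - q_t
  # descend geometrically to a finite, non-positive lower bracket
  lo <- a0 / 2; hi_neg <- a0
  repeat {
    flo <- f(lo)
    if (is.finite(flo) && flo <= 0) break
    if (!is.finite(flo)) {            # overflowed past the root: back off
      lo <- sqrt(lo * hi_neg)
      next
    }
    hi_neg <- lo
    lo <- lo / 4
    if (lo < a0 * 1e-280)
      stop("failed to bracket the implicit root above ", a0 * 1e-280,
           " at t = ", t, call. = FALSE)
  }
  if (flo == 0) return(report(lo, 0L, 0, FALSE))
  sol <- stats::uniroot(f, lower = lo, upper = a0, f.lower = flo,
                        f.upper = params$k_a_max * t,
                        tol = max(tol_abs, tol_rel * a0),
                        maxiter = max_iter)
  amount <- min(max(sol$root, lo), a0)
  # polish with Newton: the integrand gives the exact lhs derivative
  # (a^g2 + a50^g2) / a^g1, so a few steps reach machine precision
  iters <- sol$iter
  for (i in 1:3) {
    dlhs <- (amount^params$gamma2 + params$a50^params$gamma2) /
      amount^params$gamma1
    step <- f(amount) / dlhs
    if (!is.finite(step)) break
    candidate <- amount - step
    if (candidate <= 0 || candidate > a0) break
    amount <- candidate
    iters <- iters + 1L
    if (abs(step) <= .Machine$double.eps * amount) break
  }
  report(amount, iters, sol$estim.prec, FALSE)
}

#' Implicitly solved amounts on a time grid
#'
#' Vectorized convenience wrapper around [solve_amount_implicit()]
#' returning only the amounts.
#'
#' @inheritParams solve_amount_implicit
#' @param t Time(s), each \code{>= 0}.
#' @return Numeric vector of amounts, one per time.
#' @export
amount_implicit <- function(params, t, tol_rel = 1e-12, tol_abs = NULL) {
  vapply(t, function(ti)
    solve_amount_implicit(params, ti, tol_rel = tol_rel,
                          tol_abs = tol_abs)$amount, numeric(1))
}

#' @export
print.implicit_solve_report <- function(x, ...) {
  cat(sprintf(
    "implicit solve: amount = %.10g (%d iterations, bracket %.3g%s)\n",
    x$amount, x$iterations, x$bracket_width,
    if (x$hit_zero) ", absorption complete" else ""))
  invisible(x)
}
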