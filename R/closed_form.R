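#' First-order absorption amount
#'
#' Evaluates \eqn{A(t) = A_0 e^{-k_a t}}, the classical first-order
#' absorption profile.
#'
#' @param params A \code{first_order_params} object.
#' @param t Time(s), each \code{>= 0}.
#' @return Amount(s) remaining at \code{t}.
#' @examples
#' first_order_amount(first_order_params(k_a = 1/3, a0 = 150), t = 3)
#' @export
first_order_amount <- function(params, t) {
  stopifnot(inherits(params, "first_order_params"))
  check_times(t)
  params$a0 * exp(-params$k_a * t)
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("t must be finite numeric", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  invisible(t)
}

#' Integrated right-hand constants Q_b and Q_d
#'
#' The separable integration of the generalized model produces an implicit
#' relation \code{lhs(A) = Q(t)} whose right-hand side decreases linearly in
#' time with slope \code{-k_a_max}. For the two Lambert-W cases:
#' \deqn{Q_b(t) = A_0^{\gamma_2}/\gamma_2 + A_{50}^{\gamma_2} \log A_0
#'   - k_{a,max} t}
#' \deqn{Q_d(t) = \log A_0 - (A_{50}^{\gamma_2}/\gamma_2) A_0^{-\gamma_2}
#'   - k_{a,max} t}
#' Both require \code{gamma2 != 0} and \code{a0 > 0} (a logarithm of the
#' dose appears).
#'
#' @param params An \code{absorption_params} bundle.
#' @param t Time(s), each \code{>= 0}.
#' @return Numeric value(s) of the constant at \code{t}.
#' @export
q_b <- function(params, t) {
  params <- as_absorption_params(params)
  check_times(t)
  g2 <- params$gamma2
  if (g2 == 0) stop("q_b undefined for gamma2 = 0", call. = FALSE)
  if (params$a0 <= 0) stop("q_b undefined for a0 = 0", call. = FALSE)
  params$a0^g2 / g2 + params$a50^g2 * log(params$a0) - params$k_a_max * t
}

#' @rdname q_b
#' @export
q_d <- function(params, t) {
  params <- as_absorption_params(params)
  check_times(t)
  g2 <- params$gamma2
  if (g2 == 0) stop("q_d undefined for gamma2 = 0", call. = FALSE)
  if (params$a0 <= 0) stop("q_d undefined for a0 = 0", call. = FALSE)
  log(params$a0) - params$a50^g2 / g2 * params$a0^(-g2) - params$k_a_max * t
}

check_case <- function(params, expected) {
  cs <- classify_case(params)
  if (cs != expected)
    stop("parameter bundle is ", cs, ", not ", expected,
         "; use amount_closed_form() or solve_amount_implicit()",
         call. = FALSE)
  invisible(cs)
}

#' Closed-form amount for case B (gamma1 = 1, gamma2 > 0)
#'
#' The implicit relation
#' \eqn{A^{\gamma_2} e^{A^{\gamma_2}/A_{50}^{\gamma_2}} =
#' e^{\gamma_2 Q_b / A_{50}^{\gamma_2}}} inverts through the principal
#' Lambert W branch. Writing \eqn{u = (A/A_{50})^{\gamma_2}} gives
#' \eqn{u e^u = A_{50}^{-\gamma_2} e^{\gamma_2 Q_b/A_{50}^{\gamma_2}}}, so
#' \deqn{A(t) = A_{50}\,\omega\!\big((A_0/A_{50})^{\gamma_2}
#'   + \gamma_2\log(A_0/A_{50})
#'   - \gamma_2 k_{a,max} t / A_{50}^{\gamma_2}\big)^{1/\gamma_2},}
#' evaluated via the Wright omega function so the W argument never
#' overflows.
#'
#' @param params An \code{absorption_params} bundle classified as
#'   \code{CASE_B_LAMBERT} (with \code{a0 > 0}).
#' @param t Time(s), each \code{>= 0}.
#' @return Amount(s) \code{A(t)}, strictly decreasing, in \code{(0, a0]}.
#' @export
amount_case_b <- function(params, t) {
  params <- as_absorption_params(params)
  check_case(params, "CASE_B_LAMBERT")
  check_times(t)
  if (params$a0 <= 0) stop("amount_case_b requires a0 > 0", call. = FALSE)
  g2 <- params$gamma2
  r <- params$a0 / params$a50
  z <- r^g2 + g2 * log(r) - g2 * params$k_a_max * t / params$a50^g2
  params$a50 * wright_omega(z)^(1 / g2)
}

#' Michaelis-Menten absorption amount
#'
#' The \code{gamma1 = gamma2 = 1} member of the family:
#' \eqn{dA/dt = -k_{a,max} A/(A + A_{50})}, with closed form
#' \eqn{A = A_{50} W\!\big(A_{50}^{-1} e^{Q_b/A_{50}}\big)}. This is the
#' case-B formula specialized to \code{gamma2 = 1} and shares its code
#' path, so the two agree bit-for-bit.
#'
#' @inheritParams amount_case_b
#' @return Amount(s) \code{A(t)}.
#' @export
michaelis_menten_amount <- function(params, t) {
  params <- as_absorption_params(params)
  if (params$gamma1 != 1 || params$gamma2 != 1)
    stop("michaelis_menten_amount requires gamma1 = gamma2 = 1",
         call. = FALSE)
  amount_case_b(params, t)
}

#' Closed-form amount for case C (gamma1 = 1, gamma2 = 0)
#'
#' With \code{gamma2 = 0} the denominator is the constant 2, so the model
#' is exactly first-order with effective rate constant
#' \code{k_a = k_a_max / 2}.
#'
#' @inheritParams amount_case_b
#' @return Amount(s) \code{A(t) = a0 exp(-k_a_max t / 2)}.
#' @export
amount_case_c <- function(params, t) {
  params <- as_absorption_params(params)
  check_case(params, "CASE_C_FIRST_ORDER")
  check_times(t)
  if (params$a0 == 0) return(rep(0, length(t)))
  first_order_amount(first_order_params(params$k_a_max / 2, params$a0), t)
}

#' Closed-form amount for case D (gamma1 != 1, gamma2 = gamma1 - 1 > 0)
#'
#' The implicit relation
#' \eqn{A^{-\gamma_2} e^{A_{50}^{\gamma_2} A^{-\gamma_2}} = e^{-\gamma_2 Q_d}}
#' inverts through Lambert W: with \eqn{v = (A_{50}/A)^{\gamma_2}},
#' \eqn{v e^v = A_{50}^{\gamma_2} e^{-\gamma_2 Q_d}}, so
#' \deqn{A(t) = A_{50}\,/\,\omega\!\big((A_{50}/A_0)^{\gamma_2}
#'   + \gamma_2\log(A_{50}/A_0)
#'   + \gamma_2 k_{a,max} t\big)^{1/\gamma_2}.}
#'
#' @param params An \code{absorption_params} bundle classified as
#'   \code{CASE_D_LAMBERT} (with \code{a0 > 0}).
#' @param t Time(s), each \code{>= 0}.
#' @return Amount(s) \code{A(t)}, strictly decreasing, in \code{(0, a0]}.
#' @export
amount_case_d <- function(params, t) {
  params <- as_absorption_params(params)
  check_case(params, "CASE_D_LAMBERT")
  check_times(t)
  if (params$a0 <= 0) stop("amount_case_d requires a0 > 0", call. = FALSE)
  g2 <- params$gamma2
  r <- params$a50 / params$a0
  z <- r^g2 + g2 * log(r) + g2 * params$k_a_max * t
  params$a50 / wright_omega(z)^(1 / g2)
}

#' Closed-form amount for the power-law case (gamma1 != 1, gamma2 = 0)
#'
#' With \code{gamma2 = 0} the rate is \eqn{-k_{a,max} A^{\gamma_1}/2}, whose
#' separable solution is
#' \deqn{A(t) = \big[A_0^{1-\gamma_1}
#'   - (1-\gamma_1) k_{a,max} t / 2\big]^{1/(1-\gamma_1)}}
#' while the bracket is positive, and 0 afterwards. For \code{gamma1 < 1}
#' the amount reaches exactly zero at the finite end time
#' \eqn{t_{end} = 2 A_0^{1-\gamma_1} / ((1-\gamma_1) k_{a,max})}; for
#' \code{gamma1 > 1} absorption never completes.
#'
#' @inheritParams amount_case_b
#' @return Amount(s) \code{A(t)}, clamped at 0 after the end time.
#' @export
amount_power_law <- function(params, t) {
  params <- as_absorption_params(params)
  check_case(params, "POWER_LAW")
  check_times(t)
  if (params$a0 == 0) return(rep(0, length(t)))
  g1 <- params$gamma1
  base <- params$a0^(1 - g1) - (1 - g1) * params$k_a_max * t / 2
  ifelse(base <= 0, 0, base^(1 / (1 - g1)))
}

#' Closed-form amount, dispatched by analytic case
#'
#' Routes a parameter bundle to its exact solution
#' ([amount_case_b()], [amount_case_c()], [amount_case_d()] or
#' [amount_power_law()]). Bundles in the general implicit regime
#' (\code{CASE_A_IMPLICIT}) have no closed form; use
#' [solve_amount_implicit()] for those.
#'
#' @param params An \code{absorption_params} bundle.
#' @param t Time(s), each \code{>= 0}.
#' @return Amount(s) \code{A(t)}.
#' @examples
#' p <- absorption_params(k_a_max = 25, a50 = 75, gamma1 = 1, gamma2 = 1,
#'                        a0 = 150)
#' amount_closed_form(p, c(0, 1, 6, 24))
#' @export
amount_closed_form <- function(params, t) {
  params <- as_absorption_params(params)
  check_times(t)
  if (params$a0 == 0) return(rep(0, length(t)))
  cs <- classify_case(params)
  switch(cs,
    CASE_B_LAMBERT = amount_case_b(params, t),
    CASE_C_FIRST_ORDER = amount_case_c(params, t),
    CASE_D_LAMBERT = amount_case_d(params, t),
    POWER_LAW = amount_power_law(params, t),
    stop("no closed form for this bundle (", cs,
         "); use solve_amount_implicit()", call. = FALSE))
}
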