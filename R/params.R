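#' Parameter bundle for the generalized saturable absorption model
#'
#' Constructs and validates the parameter set of the generalized Hill-type
#' absorption model
#' \deqn{dA/dt = -K_{a,max} \frac{A^{\gamma_1}}{A^{\gamma_2} + A_{50}^{\gamma_2}},}
#' where \eqn{A(t)} is the amount of drug remaining to be absorbed at time
#' \eqn{t} and \eqn{A(0) = A_0}. Setting \code{gamma1 == gamma2} recovers
#' classical Hill kinetics; \code{gamma1 = gamma2 = 1} is Michaelis-Menten;
#' \code{gamma1 = 1, gamma2 = 0} collapses to first-order absorption with
#' rate constant \code{k_a_max / 2}.
#'
#' @param k_a_max Maximum absorption rate constant. Must be positive. Its
#'   dimensional convention is amount^(1 + gamma2 - gamma1) / time, so that
#'   the right-hand side always has units of amount / time.
#' @param a50 Amount at which the absorption rate is half of its maximum
#'   (saturation midpoint). Must be positive.
#' @param gamma1 Numerator Hill exponent (dimensionless, finite).
#' @param gamma2 Denominator Hill exponent (dimensionless, finite,
#'   non-negative; negative values are rejected because the closed-form
#'   branch structure and the meaning of \code{a50} are only established
#'   for \code{gamma2 >= 0}).
#' @param a0 Initial amount given as dose. Must be non-negative; a zero
#'   dose yields the identically-zero profile everywhere downstream.
#'
#' @return An object of class \code{absorption_params}: a validated list
#'   with elements \code{k_a_max}, \code{a50}, \code{gamma1}, \code{gamma2},
#'   \code{a0}.
#' @examples
#' p <- absorption_params(k_a_max = 25, a50 = 75, gamma1 = 1, gamma2 = 1,
#'                        a0 = 150)
#' classify_case(p)
#' @export
absorption_params <- function(k_a_max, a50, gamma1, gamma2, a0) {
  p <- structure(
    list(k_a_max = as.numeric(k_a_max), a50 = as.numeric(a50),
         gamma1 = as.numeric(gamma1), gamma2 = as.numeric(gamma2),
         a0 = as.numeric(a0)),
    class = "absorption_params")
  validate_params(p)
}

#' Validate an absorption parameter bundle
#'
#' Checks every invariant of [absorption_params()] and returns the bundle
#' unchanged if all hold; otherwise stops with an error naming the violated
#' invariant.
#'
#' @param params An \code{absorption_params} object (or a bare list with the
#'   same fields).
#' @return \code{params}, invisibly unchanged, if valid.
#' @export
validate_params <- function(params) {
  for (f in c("k_a_max", "a50", "gamma1", "gamma2", "a0")) {
    v <- params[[f]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (params$k_a_max <= 0)
    stop("invariant violated: k_a_max must be > 0 (got ", params$k_a_max, ")",
         call. = FALSE)
  if (params$a50 <= 0)
    stop("invariant violated: a50 must be > 0 (got ", params$a50, ")",
         call. = FALSE)
  if (params$a0 < 0)
    stop("invariant violated: a0 must be >= 0 (got ", params$a0, ")",
         call. = FALSE)
  if (params$gamma2 < 0)
    stop("invariant violated: gamma2 must be >= 0 (negative denominator ",
         "exponents are outside the supported model family)", call. = FALSE)
  params
}

#' First-order absorption parameters
#'
#' Parameters of the classical first-order model \eqn{dA/dt = -K_a A} with
#' solution \eqn{A(t) = A_0 e^{-K_a t}}.
#'
#' @param k_a Absorption rate constant (1/time), positive.
#' @param a0 Initial amount (dose), non-negative.
#' @return An object of class \code{first_order_params}.
#' @export
first_order_params <- function(k_a, a0) {
  k_a <- as.numeric(k_a); a0 <- as.numeric(a0)
  if (!is.finite(k_a) || k_a <= 0)
    stop("invariant violated: k_a must be a finite number > 0", call. = FALSE)
  if (!is.finite(a0) || a0 < 0)
    stop("invariant violated: a0 must be a finite number >= 0", call. = FALSE)
  structure(list(k_a = k_a, a0 = a0), class = "first_order_params")
}

#' Hill-kinetics absorption parameters
#'
#' Parameters of the Hill absorption model
#' \eqn{dA/dt = -K_{a,max} A^\gamma / (A^\gamma + A_{50}^\gamma)}, i.e. the
#' \code{gamma1 == gamma2} diagonal of the generalized model.
#'
#' @param k_a_max Maximum absorption rate, positive.
#' @param a50 Saturation midpoint amount, positive.
#' @param gamma Hill exponent, positive.
#' @param a0 Initial amount, non-negative.
#' @return An object of class \code{hill_params}.
#' @export
hill_params <- function(k_a_max, a50, gamma, a0) {
  if (!is.finite(gamma) || gamma <= 0)
    stop("invariant violated: gamma must be a finite number > 0", call. = FALSE)
  p <- absorption_params(k_a_max, a50, gamma, gamma, a0)
  structure(list(k_a_max = p$k_a_max, a50 = p$a50, gamma = as.numeric(gamma),
                 a0 = p$a0), class = "hill_params")
}

#' Convert Hill parameters to the generalized bundle
#'
#' @param params A \code{hill_params} object.
#' @return The equivalent \code{absorption_params} with
#'   \code{gamma1 = gamma2 = gamma}.
#' @export
as_absorption_params <- function(params) {
  if (inherits(params, "absorption_params")) return(params)
  if (inherits(params, "hill_params"))
    return(absorption_params(params$k_a_max, params$a50, params$gamma,
                             params$gamma, params$a0))
  if (inherits(params, "first_order_params"))
    return(absorption_params(2 * params$k_a, 1, 1, 0, params$a0))
  validate_params(structure(params, class = "absorption_params"))
}

#' Model case labels
#'
#' The analytic-solvability regimes of the generalized model. Exactly one
#' label applies to every valid parameter bundle:
#' \describe{
#'   \item{CASE_B_LAMBERT}{\code{gamma1 = 1, gamma2 > 0}: Lambert-W closed
#'     form (includes Michaelis-Menten at \code{gamma2 = 1}).}
#'   \item{CASE_C_FIRST_ORDER}{\code{gamma1 = 1, gamma2 = 0}: reduces to
#'     first-order absorption with \code{k_a = k_a_max / 2}.}
#'   \item{CASE_D_LAMBERT}{\code{gamma1 != 1, gamma2 - gamma1 = -1,
#'     gamma2 > 0}: Lambert-W closed form.}
#'   \item{POWER_LAW}{\code{gamma1 != 1, gamma2 = 0}: explicit power-law
#'     solution, with finite absorption end time when \code{gamma1 < 1}.}
#'   \item{CASE_A_IMPLICIT}{everything else: no closed form in elementary
#'     or Lambert-W terms; solved by monotone root-finding
#'     (see [solve_amount_implicit()]).}
#' }
#' @name model_case
NULL

MODEL_CASES <- c("CASE_A_IMPLICIT", "CASE_B_LAMBERT", "CASE_C_FIRST_ORDER",
                 "CASE_D_LAMBERT", "POWER_LAW")

#' Classify a parameter bundle into its analytic case
#'
#' Determines which solution regime a generalized-model parameter bundle
#' falls into (see [model_case]). Equality of floating-point exponents is
#' tested within a tolerance band.
#'
#' @param params An \code{absorption_params} bundle.
#' @param tol Non-negative tolerance for exponent-equality tests
#'   (default \code{1e-12}).
#' @return One of \code{"CASE_A_IMPLICIT"}, \code{"CASE_B_LAMBERT"},
#'   \code{"CASE_C_FIRST_ORDER"}, \code{"CASE_D_LAMBERT"},
#'   \code{"POWER_LAW"}.
#' @examples
#' classify_case(absorption_params(1, 1, 1, 0, 10))  # first order
#' classify_case(absorption_params(1, 1, 2, 1, 10))  # case D
#' @export
classify_case <- function(params, tol = 1e-12) {
  params <- as_absorption_params(params)
  stopifnot(is.numeric(tol), length(tol) == 1L, tol >= 0)
  g1 <- params$gamma1; g2 <- params$gamma2
  g1_is_one <- abs(g1 - 1) <= tol
  g2_is_zero <- abs(g2) <= tol
  if (g1_is_one && g2_is_zero) return("CASE_C_FIRST_ORDER")
  if (g1_is_one && g2 > tol) return("CASE_B_LAMBERT")
  if (!g1_is_one && abs(g2 - g1 + 1) <= tol && g2 > tol)
    return("CASE_D_LAMBERT")
  if (!g1_is_one && g2_is_zero) return("POWER_LAW")
  "CASE_A_IMPLICIT"
}

#' Absorption rate of the generalized model
#'
#' Evaluates the right-hand side
#' \eqn{dA/dt = -k_{a,max} a^{\gamma_1} / (a^{\gamma_2} + a_{50}^{\gamma_2})}
#' at one or more amounts. The rate is never positive: the amount remaining
#' to be absorbed can only decrease.
#'
#' @param params An \code{absorption_params} bundle.
#' @param a Amount(s), each \code{>= 0}.
#' @return Rate(s) \code{dA/dt}, all \code{<= 0}.
#' @export
rhs_modified <- function(params, a) {
  params <- as_absorption_params(params)
  if (any(a < 0)) stop("amount a must be >= 0", call. = FALSE)
  if (params$gamma1 <= 0 && any(a == 0))
    stop("rate has a pole at a = 0 when gamma1 <= 0", call. = FALSE)
  num <- ifelse(a == 0, 0, a^params$gamma1)
  -params$k_a_max * num / (a^params$gamma2 + params$a50^params$gamma2)
}

#' Absorption rate of the Hill model
#'
#' Evaluates \eqn{dA/dt = -k_{a,max} a^\gamma / (a^\gamma + a_{50}^\gamma)};
#' identical to [rhs_modified()] on the \code{gamma1 = gamma2} diagonal.
#' At \code{a = a50} the rate equals \code{-k_a_max / 2} for every gamma:
#' that is what defines the saturation midpoint.
#'
#' @param params A \code{hill_params} object.
#' @param a Amount(s), each \code{>= 0}.
#' @return Rate(s) \code{dA/dt}.
#' @export
rhs_hill <- function(params, a) {
  stopifnot(inherits(params, "hill_params"))
  rhs_modified(as_absorption_params(params), a)
}

#' @export
print.absorption_params <- function(x, ...) {
  cat("Generalized saturable absorption parameters\n")
  cat(sprintf("  k_a_max = %g, a50 = %g, gamma1 = %g, gamma2 = %g, a0 = %g\n",
              x$k_a_max, x$a50, x$gamma1, x$gamma2, x$a0))
  cat("  analytic case:", classify_case(x), "\n")
  invisible(x)
}

#' Read or write a parameter bundle as JSON
#'
#' Serializes an \code{absorption_params} bundle to a JSON object with keys
#' \code{k_a_max}, \code{a50}, \code{gamma1}, \code{gamma2}, \code{a0}, or
#' reads one back.
#'
#' @param params Bundle to write.
#' @param path File path.
#' @return \code{params_to_json} returns \code{path} invisibly;
#'   \code{params_from_json} returns the validated bundle.
#' @export
params_to_json <- function(params, path) {
  params <- as_absorption_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  absorption_params(x$k_a_max, x$a50, x$gamma1, x$gamma2, x$a0)
}
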