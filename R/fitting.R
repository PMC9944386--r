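# Model evaluation used everywhere downstream: exact closed form when the
# bundle admits one, monotone implicit inversion otherwise.
amount_model <- function(params, t) {
  if (classify_case(params) == "CASE_A_IMPLICIT")
    amount_implicit(params, t)
  else
    amount_closed_form(params, t)
}

#' Amount-time observations
#'
#' Container for observed (or simulated) remaining-amount data. Rows are
#' sorted by time on construction, so fitting is invariant to the input
#' row order.
#'
#' @param times Observation times, non-negative.
#' @param amounts Observed remaining amounts, non-negative.
#' @param noise_model One of \code{"none"}, \code{"additive"},
#'   \code{"proportional"} (metadata describing how the data were made).
#' @param noise_scale Noise scale: an amount (additive) or a fraction
#'   (proportional).
#' @param seed Integer seed used to generate the data, or \code{NULL}.
#' @return An object of class \code{observations}.
#' @export
observations <- function(times, amounts, noise_model = "none",
                         noise_scale = 0, seed = NULL) {
  stopifnot(length(times) == length(amounts),
            is.numeric(times), is.numeric(amounts),
            all(is.finite(times)), all(is.finite(amounts)),
            all(times >= 0), all(amounts >= 0),
            noise_model %in% c("none", "additive", "proportional"),
            noise_scale >= 0)
  o <- order(times)
  structure(list(times = as.numeric(times[o]),
                 amounts = as.numeric(amounts[o]),
                 noise_model = noise_model, noise_scale = noise_scale,
                 seed = seed),
            class = "observations")
}

#' Simulate noisy amount-time observations
#'
#' Evaluates the model at the given times (closed form where available,
#' implicit solver otherwise) and adds measurement noise: Gaussian with
#' standard deviation \code{noise_scale} (additive) or
#' \code{noise_scale * A(t)} (proportional). Draws that land negative are
#' resampled up to 100 times, then clamped to 0, so amounts remain
#' physical. A given seed reproduces the data exactly; the caller's random
#' number stream is left untouched.
#'
#' @param params An \code{absorption_params} bundle (the truth).
#' @param times Observation times.
#' @param noise_model \code{"none"}, \code{"additive"} or
#'   \code{"proportional"}.
#' @param noise_scale Non-negative noise scale.
#' @param seed Optional integer seed.
#' @return An [observations()] object.
#' @examples
#' p <- absorption_params(25, 75, 1, 1, 150)
#' obs <- simulate_observations(p, times = 1:10,
#'                              noise_model = "proportional",
#'                              noise_scale = 0.02, seed = 7)
#' @export
simulate_observations <- function(params, times,
                                  noise_model = c("none", "additive",
                                                  "proportional"),
                                  noise_scale = 0, seed = NULL) {
  params <- as_absorption_params(params)
  noise_model <- match.arg(noise_model)
  check_times(times)
  stopifnot(noise_scale >= 0)
  truth <- amount_model(params, times)
  if (noise_model == "none" || noise_scale == 0)
    return(observations(times, truth, noise_model, noise_scale, seed))
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  sd <- switch(noise_model,
               additive = rep(noise_scale, length(truth)),
               proportional = noise_scale * truth)
  amounts <- stats::rnorm(length(truth), truth, sd)
  for (i in which(amounts < 0)) {
    for (try in 1:100) {
      amounts[i] <- stats::rnorm(1, truth[i], sd[i])
      if (amounts[i] >= 0) break
    }
    if (amounts[i] < 0) amounts[i] <- 0
  }
  observations(times, amounts, noise_model, noise_scale, seed)
}

#' Fit absorption parameters to amount-time observations
#'
#' Least-squares estimation of generalized-model parameters. Residuals are
#' computed between observed amounts and the model evaluated through the
#' fast closed forms (or the implicit solver in the general regime), and
#' minimized with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]). Free parameters are optimized on the log
#' scale, which enforces positivity without constraints.
#'
#' Two loss functions are offered: ordinary least squares on amounts
#' (\code{"ols"}, suited to additive error) and least squares on log
#' amounts (\code{"log"}, suited to proportional error; observations at or
#' below zero are dropped from a log fit with a warning).
#'
#' @param obs An [observations()] object.
#' @param free Character vector naming the free parameters, a subset of
#'   \code{c("k_a_max", "a50", "gamma1", "gamma2")}. The dose \code{a0} is
#'   always treated as known. Default \code{c("k_a_max", "a50")}; freeing
#'   the exponents as well is supported but weakly identified on sparse
#'   designs.
#' @param fixed Named list giving every parameter not in \code{free}
#'   (must include \code{a0}).
#' @param init Optional named list of starting values for free parameters.
#'   Defaults: \code{k_a_max} from a secant slope over the earliest
#'   observations, \code{a50} at the mid-range of observed amounts,
#'   exponents at 1.
#' @param loss \code{"ols"} or \code{"log"}.
#' @param max_iter Maximum optimizer iterations (default 200).
#' @return An object of class \code{absorption_fit}: list with
#'   \code{estimates} (an \code{absorption_params}), \code{free},
#'   \code{residual_norm} (sum of squared amount-scale residuals),
#'   \code{converged}, \code{n_iter}, \code{covariance_proxy} (approximate
#'   standard error per free parameter, from the local curvature), and
#'   \code{loss}.
#' @examples
#' p <- absorption_params(25, 75, 1, 1, 150)
#' obs <- simulate_observations(p, times = seq(0.5, 24, length.out = 12))
#' fit <- fit_params(obs, free = c("k_a_max", "a50"),
#'                   fixed = list(gamma1 = 1, gamma2 = 1, a0 = 150))
#' fit$estimates
#' @export
fit_params <- function(obs, free = c("k_a_max", "a50"), fixed = list(),
                       init = NULL, loss = c("ols", "log"),
                       max_iter = 200L) {
  stopifnot(inherits(obs, "observations"))
  loss <- match.arg(loss)
  all_names <- c("k_a_max", "a50", "gamma1", "gamma2")
  if (!all(free %in% all_names) || anyDuplicated(free))
    stop("free must be a subset of ", paste(all_names, collapse = ", "),
         call. = FALSE)
  if (is.null(fixed$a0))
    stop("fixed$a0 (the dose) is required: a0 is treated as known",
         call. = FALSE)
  missing_fixed <- setdiff(all_names, c(free, names(fixed)))
  if (length(missing_fixed))
    stop("parameters neither free nor fixed: ",
         paste(missing_fixed, collapse = ", "), call. = FALSE)

  t_obs <- obs$times; a_obs <- obs$amounts
  n_free <- length(free)
  if (length(t_obs) < n_free + 1)
    stop("non-identifiable design: need at least ", n_free + 1,
         " observations for ", n_free, " free parameters", call. = FALSE)
  if (length(unique(t_obs)) < 2 || stats::sd(a_obs) == 0)
    stop("non-identifiable design: observations carry no time-amount ",
         "information (constant amounts or a single time point)",
         call. = FALSE)

  start <- default_init(t_obs, a_obs, free, fixed)
  if (!is.null(init))
    for (nm in intersect(names(init), free)) start[[nm]] <- init[[nm]]
  start_log <- log(unlist(start[free]))

  build <- function(theta_log) {
    vals <- as.list(exp(theta_log))
    names(vals) <- free
    p <- utils::modifyList(fixed, vals)
    absorption_params(p$k_a_max, p$a50, p$gamma1, p$gamma2, fixed$a0)
  }
  keep <- if (loss == "log") a_obs > 0 else rep(TRUE, length(a_obs))
  if (loss == "log" && !all(keep))
    warning("dropping ", sum(!keep),
            " non-positive observation(s) from the log-scale fit")
  resid_fn <- function(theta_log) {
    p <- tryCatch(build(theta_log), error = function(e) NULL)
    if (is.null(p)) return(rep(1e8, sum(keep)))
    pred <- tryCatch(amount_model(p, t_obs[keep]),
                     error = function(e) rep(NA_real_, sum(keep)))
    if (any(!is.finite(pred))) return(rep(1e8, sum(keep)))
    if (loss == "log") log(pmax(pred, 1e-300)) - log(a_obs[keep])
    else pred - a_obs[keep]
  }

  fit <- minpack.lm::nls.lm(par = start_log, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-14,
                              ptol = 1e-14))
  est <- build(fit$par)
  resid_amt <- amount_model(est, t_obs) - a_obs
  se <- tryCatch({
    dof <- max(sum(keep) - n_free, 1)
    s2 <- fit$deviance / dof
    cov_log <- s2 * solve(fit$hessian)
    se_log <- sqrt(pmax(diag(cov_log), 0))
    se_nat <- se_log * exp(fit$par)          # delta method back from log
    names(se_nat) <- free
    se_nat
  }, error = function(e) NULL)
  structure(list(estimates = est, free = free,
                 residual_norm = sum(resid_amt^2),
                 converged = fit$info %in% 1:4,
                 n_iter = fit$niter,
                 covariance_proxy = se, loss = loss),
            class = "absorption_fit")
}

default_init <- function(t_obs, a_obs, free, fixed) {
  start <- fixed
  if ("k_a_max" %in% free) {
    o <- order(t_obs)
    i1 <- o[1]; i2 <- o[min(2, length(o))]
    slope <- (a_obs[i1] - a_obs[i2]) / max(t_obs[i2] - t_obs[i1], 1e-6)
    start$k_a_max <- max(abs(slope), 1e-3)   # crude early-time secant
  }
  if ("a50" %in% free)
    start$a50 <- max((max(a_obs) + min(a_obs)) / 2, 1e-3)
  if ("gamma1" %in% free) start$gamma1 <- 1
  if ("gamma2" %in% free) start$gamma2 <- 1
  start
}

#' @export
print.absorption_fit <- function(x, ...) {
  e <- x$estimates
  cat("Absorption model fit (", x$loss, " loss)\n", sep = "")
  cat(sprintf("  k_a_max = %.6g, a50 = %.6g, gamma1 = %.4g, gamma2 = %.4g, a0 = %g\n",
              e$k_a_max, e$a50, e$gamma1, e$gamma2, e$a0))
  cat(sprintf("  free: %s; residual norm = %.6g; converged: %s (%d iterations)\n",
              paste(x$free, collapse = ", "), x$residual_norm,
              x$converged, x$n_iter))
  if (!is.null(x$covariance_proxy))
    cat("  approx. s.e.:",
        paste(sprintf("%s = %.3g", names(x$covariance_proxy),
                      x$covariance_proxy), collapse = ", "), "\n")
  invisible(x)
}

#' Read amount-time observations from CSV
#'
#' Expects a header with columns \code{time} and \code{amount}
#' (UTF-8, "." decimal separator). Malformed rows are reported with their
#' row numbers.
#'
#' @param path CSV file path.
#' @return An [observations()] object.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time", "amount"))
    if (!col %in% names(df))
      stop("CSV is missing required column '", col, "'", call. = FALSE)
  if (nrow(df) == 0)
    stop("CSV contains a header but no data rows", call. = FALSE)
  for (col in c("time", "amount")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric '", col, "' value at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    df[[col]] <- v
  }
  observations(df$time, df$amount)
}
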