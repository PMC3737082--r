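# Weighted nonlinear least-squares estimation of the two-tissue-compartment
# parameters from a frame TAC and an input function.

#' Pearson chi-squared goodness of fit
#'
#' `sum((O - E)^2 / E)` over observed and expected values. Reported as a
#' goodness-of-fit indicator alongside a fit; it is not the fit objective
#' (it is undefined where the expectation is non-positive).
#'
#' @param observed,expected numeric vectors of equal length; `expected` must
#'   be strictly positive.
#' @return Non-negative scalar.
#' @examples
#' chi_squared(c(3, 5), c(4, 4))  # 0.5
#' @export
chi_squared <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("'observed' and 'expected' must have equal length")
  if (any(expected <= 0))
    stop("chi-squared is undefined for non-positive expected values")
  sum((observed - expected)^2 / expected)
}

.default_start <- c(K1 = 0.2, k2 = 0.4, k3 = 0.05, k4 = 0.01, vb = 0.05)
.upper_bounds <- c(K1 = 5, k2 = 5, k3 = 5, k4 = 5, vb = 0.2)

#' Fit the two-tissue-compartment model to a tissue TAC
#'
#' Estimates `K1, k2, k3` (and optionally `k4` and the fractional blood
#' volume `vb`) by bounded nonlinear least squares between the measured
#' frame TAC and the model TAC computed from the plasma input function (see
#' [model_tac()]). Robustness against local minima is obtained by
#' multistart: the default start (`K1 = 0.2, k2 = 0.4, k3 = 0.05,
#' k4 = 0.01, vb = 0.05`) plus jittered restarts (+/-50%, fixed seed), each
#' optimized with the bounded PORT routine, best loss polished and kept.
#'
#' The least-squares objective uses uniform frame weights by default;
#' `weights = "duration"` weights each squared residual by the frame length
#' (approximating a time-integral criterion). The Pearson chi-squared of
#' the fit is computed at the optimum and reported separately from the
#' objective. Parameter standard errors come from the Jacobian-based
#' covariance at the optimum.
#'
#' @param tac measured [frame_tac()].
#' @param plasma plasma input function ([sampled_curve()]); interpolated
#'   linearly onto the internal 1-s grid, so subsampled input functions are
#'   accepted.
#' @param blood whole-blood curve for the blood-volume term; required when
#'   `vb > 0` or `fit_vb = TRUE`.
#' @param vb fractional blood volume held fixed (default 0.055); ignored
#'   when `fit_vb = TRUE`.
#' @param fit_vb estimate `vb` as a free parameter, bounded to `[0, 0.2]`.
#' @param fit_k4 estimate `k4` (default) or hold it at 0 (irreversible
#'   model).
#' @param weights `"uniform"` or `"duration"`.
#' @param blend blood blending convention, see [model_tac()].
#' @param start optional named vector overriding the default start.
#' @param multistart number of starts including the central one.
#' @param dt internal grid step, seconds.
#' @param jitter_seed seed for the multistart jitter.
#' @param control overrides for the `nlminb` control list.
#' @return Object of class `"fdg2tc"`; see [coef.fdg2tc()],
#'   [summary.fdg2tc()] and friends.
#' @examples
#' fx <- make_fixture(seed = 1, n_rep = 0, jitter = 0)
#' fit <- fit_fdg2tc(fx$tac, fx$plasma, fx$blood, fit_k4 = FALSE,
#'                   multistart = 1)
#' coef(fit)
#' @export
fit_fdg2tc <- function(tac, plasma, blood = NULL, vb = 0.055,
                       fit_vb = FALSE, fit_k4 = TRUE,
                       weights = c("uniform", "duration"),
                       blend = c("scale", "add"),
                       start = NULL, multistart = 5L, dt = 1,
                       jitter_seed = 42L, control = list()) {
  weights <- match.arg(weights)
  blend <- match.arg(blend)
  stopifnot(inherits(tac, "frame_tac"))
  if ((fit_vb || vb > 0) && is.null(blood))
    stop("a blood curve is required when vb > 0 or fit_vb = TRUE")
  eng <- tac_engine(plasma, blood, tac, dt = dt, blend = blend)
  y <- tac$activity
  w <- if (weights == "duration") (tac$end - tac$start) / mean(tac$end - tac$start)
       else rep(1, length(y))
  sw <- sqrt(w)

  free <- c("K1", "k2", "k3", if (fit_k4) "k4", if (fit_vb) "vb")
  fixed <- c(k4 = if (!fit_k4) 0, vb = if (!fit_vb) vb)
  full_par <- function(th) {
    p <- c(th, fixed)
    p[c("K1", "k2", "k3", "k4", "vb")]
  }
  resid_fun <- function(th) sw * (eng$eval_frames(full_par(th)) - y)
  obj <- function(th) { r <- resid_fun(th); sum(r * r) }

  start0 <- .default_start
  if (!is.null(start)) start0[names(start)] <- start
  start0 <- start0[free]
  lower <- stats::setNames(rep(0, length(free)), free)
  upper <- .upper_bounds[free]
  ctl_search <- utils::modifyList(
    list(eval.max = 2000, iter.max = 800, rel.tol = 1e-10), control)
  ctl_polish <- utils::modifyList(ctl_search, list(rel.tol = 1e-13))

  starts <- list(start0)
  if (multistart > 1L) {
    jit <- with_seed(jitter_seed, replicate(multistart - 1L, {
      s <- start0 * stats::runif(length(start0), 0.5, 1.5)
      pmin(pmax(s, lower + 1e-6), upper)
    }, simplify = FALSE))
    starts <- c(starts, jit)
  }
  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    o <- try(stats::nlminb(s, obj, lower = lower, upper = upper,
                           control = ctl_search), silent = TRUE)
    if (inherits(o, "try-error") || !is.finite(o$objective)) next
    n_conv <- n_conv + (o$convergence == 0L)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) {
    out <- list(converged = FALSE, message = "no start produced a finite loss")
    class(out) <- "fdg2tc"
    return(out)
  }
  # polish the best start at tight tolerance; starting at the optimum can
  # make nlminb report "false convergence", so convergence is judged from
  # the search stage as well
  polish <- stats::nlminb(best$par, obj, lower = lower, upper = upper,
                          control = ctl_polish)
  converged <- best$convergence == 0L || polish$convergence == 0L || n_conv > 0L
  if (polish$objective <= best$objective) best <- polish
  th <- stats::setNames(best$par, free)
  params <- as_kinetic_params(full_par(th))

  fitted_vals <- eng$eval_frames(params)
  rss <- best$objective
  n <- length(y)
  p_free <- length(free)
  # Jacobian-based covariance of the free parameters
  J <- matrix(0, n, p_free)
  eps <- pmax(abs(th), 1e-4) * 1e-6
  r0 <- resid_fun(th)
  for (j in seq_len(p_free)) {
    thj <- th
    thj[j] <- thj[j] + eps[j]
    J[, j] <- (resid_fun(thj) - r0) / eps[j]
  }
  sigma2 <- rss / max(n - p_free, 1)
  covm <- try(solve(crossprod(J)) * sigma2, silent = TRUE)
  if (inherits(covm, "try-error")) {
    covm <- matrix(NA_real_, p_free, p_free)
  }
  dimnames(covm) <- list(free, free)
  se <- sqrt(pmax(diag(covm), 0))

  chi2 <- if (all(fitted_vals > 0)) chi_squared(y, fitted_vals) else NA_real_

  out <- list(
    params = params, se = se, vcov = covm, free = free,
    chi2 = chi2, objective = rss, converged = converged,
    n_iter = best$iterations, n_starts_converged = n_conv,
    fitted = fitted_vals, residuals = y - fitted_vals,
    tac = tac, plasma = plasma, blood = blood,
    weights = weights, w = w, blend = blend, dt = dt,
    kfdg = k_fdg(params),
    options = list(vb = vb, fit_vb = fit_vb, fit_k4 = fit_k4,
                   multistart = multistart, jitter_seed = jitter_seed),
    call = match.call())
  class(out) <- "fdg2tc"
  out
}

#' Goodness-of-fit profile over fixed fractional blood volumes
#'
#' Refits the model at each value of a `vb` grid (default 0 to 0.20 in
#' steps of 0.005, 41 points) with `vb` held fixed, and reports the
#' parameters, objective and chi-squared per grid point together with the
#' grid value minimizing chi-squared.
#'
#' @inheritParams fit_fdg2tc
#' @param vb_grid fractional blood volumes to profile.
#' @param ... further arguments passed to [fit_fdg2tc()].
#' @return Data frame of class `"vb_profile"` (one row per grid value) with
#'   attributes `best_vb` (argmin chi-squared) and `best_vb_objective`
#'   (argmin least-squares objective).
#' @export
vb_profile <- function(tac, plasma, blood, vb_grid = seq(0, 0.2, by = 0.005),
                       ...) {
  if (any(vb_grid < 0 | vb_grid > 1)) stop("vb grid values must lie in [0, 1]")
  rows <- lapply(vb_grid, function(v) {
    f <- fit_fdg2tc(tac, plasma, blood, vb = v, fit_vb = FALSE, ...)
    data.frame(vb = v, K1 = f$params[["K1"]], k2 = f$params[["k2"]],
               k3 = f$params[["k3"]], k4 = f$params[["k4"]],
               kfdg = f$kfdg, chi2 = f$chi2, objective = f$objective,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_vb") <- out$vb[which.min(out$chi2)]
  attr(out, "best_vb_objective") <- out$vb[which.min(out$objective)]
  class(out) <- c("vb_profile", "data.frame")
  out
}

#' Serialize a fit as a JSON record
#'
#' @param fit an `"fdg2tc"` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fdg2tc"))
  rec <- list(
    params = as.list(unclass(fit$params)),
    se = as.list(fit$se),
    chi2 = fit$chi2,
    objective = fit$objective,
    converged = fit$converged,
    n_iter = fit$n_iter,
    kfdg = fit$kfdg,
    options = fit$options,
    digests = list(tac = digest_values(fit$tac$activity),
                   plasma = digest_values(fit$plasma$activity)))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# cheap order-dependent content digest for provenance records
digest_values <- function(x) {
  x <- round(as.numeric(x), 9)
  sprintf("%d:%0.9g:%0.9g", length(x), sum(x), sum(x * seq_along(x)))
}
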