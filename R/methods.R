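# Standard model-object methods for "fdg2tc" fits.

#' @export
print.fdg2tc <- function(x, digits = 4, ...) {
  cat("Two-tissue-compartment fit\n")
  if (is.null(x$params)) {
    cat("  not converged:", x$message, "\n")
    return(invisible(x))
  }
  print(x$params, digits = digits)
  cat(sprintf("  K(FDG) = %.*g mL/min/cm3, chi2 = %.*g, objective = %.4g\n",
              digits, x$kfdg, digits, x$chi2, x$objective))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' Extract estimated parameters
#'
#' @param object an `"fdg2tc"` fit.
#' @param ... unused.
#' @return Named vector `K1, k2, k3, k4, vb` (fixed parameters included at
#'   their fixed values).
#' @export
coef.fdg2tc <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(unclass(object$params)))
}

#' @export
vcov.fdg2tc <- function(object, ...) object$vcov

#' @export
fitted.fdg2tc <- function(object, ...) object$fitted

#' @export
residuals.fdg2tc <- function(object, ...) object$residuals

#' @export
deviance.fdg2tc <- function(object, ...) object$objective

#' Summarize a two-tissue-compartment fit
#'
#' @param object an `"fdg2tc"` fit.
#' @param glucose optional plasma glucose (mmol/L) to report CMRglc.
#' @param lc lumped constant for CMRglc (default 0.6).
#' @param ... unused.
#' @return Object of class `"summary.fdg2tc"` with a coefficient table
#'   (estimate, standard error), goodness of fit and macro-parameters.
#' @export
summary.fdg2tc <- function(object, glucose = NULL, lc = 0.6, ...) {
  est <- coef(object)
  se <- stats::setNames(rep(NA_real_, length(est)), names(est))
  se[object$free] <- object$se
  tab <- cbind(Estimate = est, `Std. Error` = se)
  out <- list(coefficients = tab, chi2 = object$chi2,
              objective = object$objective, converged = object$converged,
              n_frames = length(object$fitted), kfdg = object$kfdg,
              cmrglc = if (!is.null(glucose))
                cmr_glc(object$kfdg, glucose = glucose, lc = lc),
              options = object$options)
  class(out) <- "summary.fdg2tc"
  out
}

#' @export
print.summary.fdg2tc <- function(x, digits = 4, ...) {
  cat("Two-tissue-compartment fit summary\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "(fixed)")
  cat(sprintf("\nK(FDG) = %.*g mL/min/cm3", digits, x$kfdg))
  if (!is.null(x$cmrglc))
    cat(sprintf(", CMRglc = %.*g umol/min/100g", digits, x$cmrglc))
  cat(sprintf("\nchi2 = %.*g over %d frames; converged: %s\n",
              digits, x$chi2, x$n_frames, x$converged))
  invisible(x)
}

#' Predict the model TAC on a new frame schedule
#'
#' @param object an `"fdg2tc"` fit.
#' @param newdata a [frame_tac()] or frame schedule; default: the fitted
#'   schedule.
#' @param ... unused.
#' @return A [frame_tac()] of model activities.
#' @export
predict.fdg2tc <- function(object, newdata = NULL, ...) {
  sched <- if (is.null(newdata)) object$tac else newdata
  model_tac(object$params, object$plasma, object$blood, sched,
            dt = object$dt, blend = object$blend)
}

#' Simulate noisy TAC replicates from a fit
#'
#' Draws frame-wise Gaussian noise around the fitted model TAC with the
#' frame-duration-dependent standard deviation of the package's TAC noise
#' model (see [add_tac_noise()]).
#'
#' @param object an `"fdg2tc"` fit.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of [frame_tac()] replicates.
#' @export
simulate.fdg2tc <- function(object, nsim = 1, seed = 1L, ...) {
  base <- frame_tac(object$tac$start, object$tac$end, object$fitted,
                    allow_gaps = TRUE)
  lapply(seq_len(nsim), function(i)
    add_tac_noise(base, noise_spec(seed = seed + i - 1L)))
}

#' Plot a two-tissue-compartment fit
#'
#' Measured frame activities (points at frame midtimes), fitted model TAC
#' (line) and, below, the weighted residuals.
#'
#' @param x an `"fdg2tc"` fit.
#' @param ... passed to `plot()`.
#' @export
plot.fdg2tc <- function(x, ...) {
  mid <- (x$tac$start + x$tac$end) / 2
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(mid, x$tac$activity, pch = 1, xlab = "time (s)",
                 ylab = "activity (kBq/cm3)", main = "2TC model fit", ...)
  graphics::lines(mid, x$fitted, col = "red3")
  graphics::plot(mid, x$residuals, pch = 16, cex = 0.6, xlab = "time (s)",
                 ylab = "residual")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
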