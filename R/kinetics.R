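# Two-tissue-compartment model: impulse response, model TAC, macro-parameters.
#
# State equations (concentrations per cm3 tissue, plasma input Cp):
#   dC1/dt = K1*Cp - (k2 + k3)*C1 + k4*C2
#   dC2/dt = k3*C1 - k4*C2
# Measured signal = (1 - vb) * (C1 + C2) + vb * Cblood  (default blending).
# Rate constants are stored in the conventional per-minute units and
# converted to per-second at the convolution boundary; all times are seconds.

#' Kinetic parameters of the two-tissue-compartment model
#'
#' @param K1 plasma-to-tissue clearance, mL/min/cm3.
#' @param k2 tissue-to-plasma rate constant, 1/min.
#' @param k3 phosphorylation rate constant, 1/min.
#' @param k4 dephosphorylation rate constant, 1/min; `0` gives the
#'   irreversible model.
#' @param vb fractional blood volume of the tissue region, in `[0, 1]`.
#' @return Named numeric vector of class `"kinetic_params"`.
#' @examples
#' kinetic_params(K1 = 0.328, k2 = 0.550, k3 = 0.079)
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0, vb = 0) {
  p <- c(K1 = as.numeric(K1), k2 = as.numeric(k2), k3 = as.numeric(k3),
         k4 = as.numeric(k4), vb = as.numeric(vb))
  if (any(!is.finite(p))) stop("kinetic parameters must be finite")
  if (any(p[c("K1", "k2", "k3", "k4")] < 0))
    stop("rate constants must be non-negative")
  if (p["vb"] < 0 || p["vb"] > 1) stop("vb must lie in [0, 1]")
  class(p) <- "kinetic_params"
  p
}

#' @export
print.kinetic_params <- function(x, digits = 4, ...) {
  cat("Two-tissue-compartment parameters:\n")
  cat(sprintf("  K1 = %.*g mL/min/cm3, k2 = %.*g, k3 = %.*g, k4 = %.*g 1/min, vb = %.*g\n",
              digits, x[["K1"]], digits, x[["k2"]], digits, x[["k3"]],
              digits, x[["k4"]], digits, x[["vb"]]))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  x <- unlist(x)
  kinetic_params(x[["K1"]], x[["k2"]], x[["k3"]],
                 if ("k4" %in% names(x)) x[["k4"]] else 0,
                 if ("vb" %in% names(x)) x[["vb"]] else 0)
}

#' Impulse response of the two-tissue-compartment model
#'
#' Closed-form tissue response (free plus phosphorylated compartment) to a
#' unit Dirac impulse of plasma activity:
#' `h(t) = A1 exp(-l1 t) + A2 exp(-l2 t)` with `l1 <= l2` and
#' `A1 + A2 = K1`. With `k4 = 0` the slow rate is exactly zero (irreversible
#' trapping) and the amplitude on that term equals `K1 k3 / (k2 + k3)`, the
#' net uptake rate constant.
#'
#' @param params a [kinetic_params()] (the `vb` entry is ignored here).
#' @return List with `rates` (1/min, ascending) and `amps` (mL/min/cm3).
#'   When the two eigenvalues coincide (e.g. all rate constants zero: the
#'   pure-integrator limit) a single term is returned.
#' @examples
#' impulse_response(kinetic_params(0.328, 0.550, 0.079, 0))
#' @export
impulse_response <- function(params) {
  p <- as_kinetic_params(params)
  s <- p[["k2"]] + p[["k3"]] + p[["k4"]]
  disc <- s^2 - 4 * p[["k2"]] * p[["k4"]]
  root <- sqrt(max(disc, 0))
  l1 <- (s - root) / 2
  l2 <- (s + root) / 2
  if (root <= 1e-12 * max(s, 1)) {
    # degenerate double eigenvalue; for the 2TC system this occurs only in
    # uptake-only corners (k2 = k4 = 0 type), where h(t) = K1 * exp(-l t)
    return(list(rates = l1, amps = p[["K1"]]))
  }
  a1 <- p[["K1"]] * (p[["k3"]] + p[["k4"]] - l1) / root
  a2 <- p[["K1"]] * (l2 - p[["k3"]] - p[["k4"]]) / root
  list(rates = c(l1, l2), amps = c(a1, a2))
}

# h(t) evaluated on a grid of seconds, in per-second units.
impulse_on_grid <- function(params, t_s) {
  ir <- impulse_response(params)
  rates_s <- ir$rates / 60
  amps_s <- ir$amps / 60
  h <- numeric(length(t_s))
  for (i in seq_along(rates_s)) h <- h + amps_s[i] * exp(-rates_s[i] * t_s)
  h
}

#' Net FDG uptake rate constant
#'
#' The macro-parameter `K(FDG) = K1 k3 / (k2 + k3)`, the steady-state net
#' clearance of FDG from plasma into the phosphorylated pool. It never
#' exceeds `K1`.
#'
#' @param params a [kinetic_params()], or `K1` as a bare number.
#' @param k2,k3 rate constants (1/min) when `params` is given as `K1`.
#' @return Uptake rate constant in mL/min/cm3.
#' @examples
#' k_fdg(0.156, 0.329, 0.032)          # 0.0138
#' k_fdg(kinetic_params(0.328, 0.550, 0.079))
#' @export
k_fdg <- function(params, k2 = NULL, k3 = NULL) {
  if (inherits(params, "kinetic_params") || (is.null(k2) && is.null(k3))) {
    p <- as_kinetic_params(params)
    K1 <- p[["K1"]]; k2 <- p[["k2"]]; k3 <- p[["k3"]]
  } else K1 <- as.numeric(params)
  if (k2 < 0 || k3 < 0 || K1 < 0) stop("rate constants must be non-negative")
  if (k2 + k3 <= 0) stop("K(FDG) is undefined for k2 + k3 = 0")
  K1 * k3 / (k2 + k3)
}

#' Cerebral metabolic rate of glucose
#'
#' `CMRglc = K(FDG) / LC * Gp`, scaled to umol/min/100 g. Plasma glucose in
#' mmol/L equals umol/cm3, and tissue density is taken as 1 g/cm3, so the
#' per-100-g conversion is a factor 100.
#'
#' @param kfdg uptake rate constant, mL/min/cm3 (see [k_fdg()]).
#' @param glucose arterial plasma glucose, mmol/L.
#' @param lc lumped constant translating FDG to glucose kinetics; default
#'   0.6 as commonly used for mouse brain.
#' @return CMRglc in umol/min/100 g.
#' @examples
#' cmr_glc(0.030, glucose = 10, lc = 0.6)  # 50
#' @export
cmr_glc <- function(kfdg, glucose, lc = 0.6) {
  if (lc <= 0) stop("the lumped constant must be positive")
  if (glucose < 0) stop("plasma glucose must be non-negative")
  kfdg / lc * glucose * 100
}

# Trapezoid-weight matrix mapping a dt-spaced grid over [0, T] to frame means.
frame_average_matrix <- function(start, end, t_grid, dt) {
  n <- length(t_grid)
  W <- matrix(0, nrow = length(start), ncol = n)
  for (i in seq_along(start)) {
    i0 <- which.min(abs(t_grid - start[i]))
    i1 <- which.min(abs(t_grid - end[i]))
    if (i1 <= i0) stop("frame ", i, " is shorter than the integration step")
    idx <- i0:i1
    w <- rep(1, length(idx))
    w[c(1L, length(w))] <- 0.5
    W[i, idx] <- w * dt / (t_grid[i1] - t_grid[i0])
  }
  W
}

# FFT linear convolution of h and cp on a uniform grid with trapezoid
# end-corrections; returns the running integral (h * cp)(t_j).
convolve_grid <- function(h, cp, dt) {
  n <- length(cp)
  N <- 2^ceiling(log2(2 * n))
  z <- Re(stats::fft(stats::fft(c(h, rep(0, N - n))) *
                       stats::fft(c(cp, rep(0, N - n))), inverse = TRUE)) / N
  z[seq_len(n)] * dt - (dt / 2) * (h[1L] * cp + h * cp[1L])
}

# Shared engine: precompute everything that does not depend on the kinetic
# parameters, so the fit objective only pays one FFT per evaluation.
tac_engine <- function(plasma, blood, schedule, dt = 1,
                       blend = c("scale", "add")) {
  blend <- match.arg(blend)
  t_end <- max(schedule$end)
  check_coverage(plasma, t_end, "plasma curve")
  if (!is.null(blood)) check_coverage(blood, t_end, "blood curve")
  t_grid <- seq(0, t_end, by = dt)
  cp <- interp_curve(plasma, t_grid)
  cb <- if (is.null(blood)) numeric(length(t_grid)) else interp_curve(blood, t_grid)
  n <- length(t_grid)
  N <- 2^ceiling(log2(2 * n))
  fcp <- stats::fft(c(cp, rep(0, N - n)))
  W <- frame_average_matrix(schedule$start, schedule$end, t_grid, dt)
  blood_frames <- as.vector(W %*% cb)
  eval_frames <- function(params) {
    h <- impulse_on_grid(params, t_grid)
    z <- Re(stats::fft(fcp * stats::fft(c(h, rep(0, N - n))),
                       inverse = TRUE)) / N
    ct <- z[seq_len(n)] * dt - (dt / 2) * (h[1L] * cp + h * cp[1L])
    vb <- if (inherits(params, "kinetic_params")) params[["vb"]] else params["vb"]
    tissue <- as.vector(W %*% ct)
    if (blend == "scale") (1 - vb) * tissue + vb * blood_frames
    else tissue + vb * blood_frames
  }
  list(eval_frames = eval_frames, t_grid = t_grid, cp = cp, cb = cb,
       blood_frames = blood_frames, W = W, blend = blend, dt = dt)
}

#' Model tissue time-activity curve
#'
#' Computes the frame-averaged model TAC for a parameter set: the
#' instantaneous tissue curve is the convolution of the impulse response
#' with the plasma input on a uniform internal grid (trapezoidal
#' quadrature), blended with the whole-blood curve through the fractional
#' blood volume, then averaged over each frame.
#'
#' The default blending is `(1 - vb) * tissue + vb * blood` (the convention
#' of common kinetic-modeling tools); `blend = "add"` gives the plain
#' additive form `tissue + vb * blood` for cross-tool comparison.
#'
#' @param params a [kinetic_params()] including `vb`.
#' @param plasma plasma input function, a [sampled_curve()] covering the
#'   frame schedule.
#' @param blood whole-blood curve for the `vb` term; may be `NULL` when
#'   `vb = 0`.
#' @param schedule a [frame_tac()] or frame schedule (`start`/`end` columns).
#' @param dt internal grid step in seconds (default 1 s, the native blood
#'   sampling resolution).
#' @param blend `"scale"` or `"add"`, see Details.
#' @return A [frame_tac()] with model activities in kBq/cm3.
#' @export
model_tac <- function(params, plasma, blood = NULL, schedule, dt = 1,
                      blend = c("scale", "add")) {
  p <- as_kinetic_params(params)
  if (p[["vb"]] > 0 && is.null(blood))
    stop("a blood curve is required when vb > 0")
  eng <- tac_engine(plasma, blood, schedule, dt = dt, blend = blend)
  frame_tac(schedule$start, schedule$end, eng$eval_frames(p),
            allow_gaps = TRUE)
}
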