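# Synthetic scan generation: frame schedules, protocol input functions,
# noise injection, input-function subsampling, and self-consistent scan
# fixtures. Everything the sensitivity studies need is generated in code;
# no external data are required.

#' Administration protocol
#'
#' @param duration bolus/infusion duration in seconds; 10 s is treated as a
#'   bolus, 300 s matches the experimental infusion, 900 s is the extended
#'   protocol.
#' @param scan_length total scan length in seconds (default 2700 = 45 min).
#' @return List of class `"protocol_spec"`.
#' @export
protocol_spec <- function(duration, scan_length = 2700) {
  if (duration <= 0) stop("duration must be positive")
  if (duration >= scan_length) stop("duration must be shorter than the scan")
  structure(list(duration = duration, scan_length = scan_length),
            class = "protocol_spec")
}

as_protocol <- function(x) {
  if (inherits(x, "protocol_spec")) x else protocol_spec(x)
}

#' Noise model for simulated curves
#'
#' Gaussian noise models matched to the experimental data: the input
#' function noise SD is a constant (25-40 kBq/cm3; default the midpoint
#' 32.5) plus a fraction (4-6%; default 5%) of the simulated plasma
#' activity. The TAC noise SD per frame is the frame value times 0.8
#' divided by the frame length in seconds. Negative post-noise values are
#' kept, as a plain Gaussian generator produces them; clipping would bias
#' low-activity frames.
#'
#' @param if_const_sd constant IF noise component, kBq/cm3.
#' @param if_rel_sd relative IF noise component, fraction.
#' @param tac_factor numerator factor of the TAC noise SD.
#' @param seed RNG seed making each noise draw reproducible.
#' @return List of class `"noise_spec"`.
#' @export
noise_spec <- function(if_const_sd = 32.5, if_rel_sd = 0.05,
                       tac_factor = 0.8, seed = 1L) {
  if (if_const_sd < 0 || if_rel_sd < 0 || tac_factor < 0)
    stop("noise components must be non-negative")
  structure(list(if_const_sd = if_const_sd, if_rel_sd = if_rel_sd,
                 tac_factor = tac_factor, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Build a reconstruction frame schedule for a protocol
#'
#' Deterministic frame schedule covering the scan with 33 to 39 contiguous
#' frames: 10-s frames bracket the injection/infusion stop (from 30 s
#' before to 60 s after), at most `ceiling()`-split pre-stop frames before
#' them, then a graded tail (10 x 30 s, 6 x 60 s, 4 x 120 s, remainder in
#' <= 240-s frames). Shortest frames are exactly 10 s, longest at most
#' 240 s.
#'
#' @param protocol a [protocol_spec()] or a duration in seconds.
#' @return A [frame_tac()] with `NA` activities (a bare schedule).
#' @export
make_frame_schedule <- function(protocol) {
  pr <- as_protocol(protocol)
  stop_t <- pr$duration
  total <- pr$scan_length
  pre <- numeric(0)
  peak_from <- max(0, stop_t - 30)
  if (peak_from > 0) {
    n_pre <- max(1L, ceiling(peak_from / 240))
    pre <- rep(peak_from / n_pre, n_pre)
    if (any(pre < 10)) stop("infeasible schedule: pre-stop frames shorter than 10 s")
  }
  peak_to <- min(stop_t + 60, total)
  peak <- rep(10, round((peak_to - peak_from) / 10))
  tail_len <- total - peak_from - sum(peak)
  grad <- c(rep(30, 10), rep(60, 6), rep(120, 4))
  rest <- tail_len - sum(grad)
  if (rest < 0) stop("infeasible schedule: scan too short for the graded tail")
  n240 <- floor(rest / 240)
  rem <- rest - 240 * n240
  tail_frames <- c(grad, rep(240, n240))
  if (rem > 0) {
    if (rem < 10) {
      # avoid a sub-10-s trailing frame: split the last 240-s slot
      tail_frames <- c(grad, rep(240, n240 - 1), (240 + rem) / 2, (240 + rem) / 2)
    } else tail_frames <- c(tail_frames, rem)
  }
  dur <- c(pre, peak, tail_frames)
  ends <- cumsum(dur)
  n <- length(dur)
  if (n < 33 || n > 39)
    stop("infeasible schedule: ", n, " frames falls outside 33..39")
  frame_tac(c(0, ends[-n]), ends)
}

#' Simulate a noise-free protocol input function
#'
#' Evaluates a tri-exponential input function, rescaled to the protocol
#' duration at equal dose (see [rescale_protocol()]), on a uniform grid
#' over the scan.
#'
#' @param p a [triexp_if()]; its amplitudes are rescaled so the total
#'   infused dose matches the protocol regardless of `p$t_i`.
#' @param protocol a [protocol_spec()] or duration in seconds.
#' @param dt sampling interval in seconds (default 1).
#' @return A plasma [sampled_curve()].
#' @export
simulate_if <- function(p, protocol, dt = 1) {
  pr <- as_protocol(protocol)
  p <- rescale_protocol(p, pr$duration)
  tt <- seq(0, pr$scan_length, by = dt)
  sampled_curve(tt, triexp_value(p, tt), kind = "plasma")
}

#' Add measurement noise to a curve
#'
#' `add_if_noise()` adds Gaussian noise with SD
#' `if_const_sd + if_rel_sd * value` to each sample of an input-function
#' curve; `add_tac_noise()` adds Gaussian noise with SD
#' `value * tac_factor / frame_length_s` to each frame of a TAC. Both are
#' deterministic for a given `spec$seed` and restore the caller's RNG
#' state.
#'
#' @param curve a [sampled_curve()].
#' @param tac a [frame_tac()].
#' @param spec a [noise_spec()].
#' @return Curve of the same type with noise added.
#' @export
add_if_noise <- function(curve, spec = noise_spec()) {
  stopifnot(inherits(curve, "sampled_curve"), inherits(spec, "noise_spec"))
  sd <- spec$if_const_sd + spec$if_rel_sd * curve$activity
  noisy <- with_seed(spec$seed,
                     curve$activity + stats::rnorm(nrow(curve), 0, sd))
  sampled_curve(curve$time, noisy, kind = attr(curve, "kind"))
}

#' @rdname add_if_noise
#' @export
add_tac_noise <- function(tac, spec = noise_spec()) {
  stopifnot(inherits(tac, "frame_tac"), inherits(spec, "noise_spec"))
  sd <- abs(tac$activity) * spec$tac_factor / (tac$end - tac$start)
  noisy <- with_seed(spec$seed,
                     tac$activity + stats::rnorm(nrow(tac), 0, sd))
  frame_tac(tac$start, tac$end, noisy, allow_gaps = TRUE)
}

#' Subsample an input function to a longer sampling interval
#'
#' Emulates less frequent blood sampling by deleting samples between the
#' retained time points `0, interval, 2*interval, ...` (no interpolation;
#' the fit layer interpolates linearly onto its internal grid).
#'
#' @param curve a [sampled_curve()] on a uniform native grid.
#' @param interval retained sampling interval in seconds; must be a
#'   multiple of the native spacing.
#' @return The subsampled [sampled_curve()].
#' @export
subsample_if <- function(curve, interval) {
  step <- diff(curve$time)
  native <- step[1L]
  if (any(abs(step - native) > 1e-9))
    stop("subsample_if requires a uniformly sampled curve")
  if (abs(interval / native - round(interval / native)) > 1e-9)
    stop("interval must be a multiple of the native spacing")
  m <- (curve$time - curve$time[1L]) %% interval
  keep <- pmin(m, interval - m) < 1e-6
  sampled_curve(curve$time[keep], curve$activity[keep],
                kind = attr(curve, "kind"))
}

# Canonical fixture input function: a package convention for synthetic
# scans (per-scan fitted IF parameters are not available from data).
# Rates (3, 0.3, 0.01) 1/min; effective component weights in ratio
# 800:1000:8800, scaled so the noise-free 300-s-infusion plasma curve
# peaks at `peak` kBq/cm3. The weight split is chosen for realism of the
# curve shape: a fast equilibration component, an intermediate clearance
# component, and a slow tail that leaves the plasma activity near 15% of
# the peak at the end of a 45-min scan, as observed for FDG infusion
# protocols in mice. Note the implied extrapolated steady state A+B+Z is
# several times the peak, since the slow pool is far from saturation
# after a 5-min infusion.
#' Canonical tri-exponential input function for synthetic scans
#'
#' @param peak plasma activity at the 300-s infusion stop, kBq/cm3.
#' @param t_i infusion duration the amplitudes are referenced to, seconds.
#' @return A [triexp_if()].
#' @export
canonical_triexp <- function(peak = 2000, t_i = 300) {
  rates <- c(3, 0.3, 0.01)
  w <- c(800, 1000, 8800)
  # peak of the unit-scale curve at the 300-s reference stop
  sat <- 1 - exp(-rates * 300 / 60)
  w <- w * peak / sum(w * sat)
  amps <- sum(w) * (w / rates) / sum(w / rates)
  p <- triexp_if(amps[1], amps[2], amps[3], rates[1], rates[2], rates[3],
                 t_i = 300)
  if (t_i != 300) p <- rescale_protocol(p, t_i) else p
}

#' Generate a self-consistent synthetic scan
#'
#' Builds everything a study needs for one "scan": the canonical
#' tri-exponential input function rescaled to the protocol, the noise-free
#' plasma and matched whole-blood curve (via the mouse blood-cell-uptake
#' correction), the frame schedule, the noise-free model TAC from the true
#' parameters, one noisy input function, and `n_rep` noisy TAC replicates
#' (the simulation design: one IF and ten TACs per scan).
#'
#' True parameters center on `K1 = 0.328, k2 = 0.550, k3 = 0.079, k4 = 0,
#' vb = 0.055` (a typical experimental rate-constant set); with
#' `jitter > 0`, K1, k2 and k3 are drawn uniformly within `+/- jitter`
#' (fractional) of the center, emulating between-animal variability.
#'
#' @param seed integer seed; fixes the parameter draw and all noise.
#' @param protocol a [protocol_spec()] or duration in seconds.
#' @param n_rep number of noisy TAC replicates.
#' @param jitter fractional half-width of the uniform parameter draw.
#' @param noise a [noise_spec()]; its seed is re-derived from `seed`.
#' @param peak canonical input-function peak, kBq/cm3.
#' @return List of class `"fdg_scan"` with elements `triexp`, `protocol`,
#'   `schedule`, `plasma`, `blood`, `truth`, `tac`, `if_noisy`,
#'   `tac_noisy` (list), `noise`, `seed`.
#' @export
make_fixture <- function(seed = 1L, protocol = 300, n_rep = 10L,
                         jitter = 0.05, noise = noise_spec(), peak = 2000) {
  pr <- as_protocol(protocol)
  center <- c(K1 = 0.328, k2 = 0.550, k3 = 0.079)
  drawn <- if (jitter > 0) {
    with_seed(seed, center * stats::runif(3, 1 - jitter, 1 + jitter))
  } else center
  truth <- kinetic_params(drawn[["K1"]], drawn[["k2"]], drawn[["k3"]],
                          k4 = 0, vb = 0.055)
  tri <- canonical_triexp(peak = peak)
  plasma <- simulate_if(tri, pr)
  blood <- blood_from_plasma(plasma, "mouse_exp")
  schedule <- make_frame_schedule(pr)
  tac <- model_tac(truth, plasma, blood, schedule)
  if_spec <- noise_spec(noise$if_const_sd, noise$if_rel_sd,
                        noise$tac_factor, seed = seed * 1000L + 1L)
  if_noisy <- add_if_noise(plasma, if_spec)
  tac_noisy <- lapply(seq_len(n_rep), function(i)
    add_tac_noise(tac, noise_spec(noise$if_const_sd, noise$if_rel_sd,
                                  noise$tac_factor,
                                  seed = seed * 1000L + 1L + i)))
  structure(list(triexp = rescale_protocol(tri, pr$duration), protocol = pr,
                 schedule = schedule, plasma = plasma, blood = blood,
                 truth = truth, tac = tac, if_noisy = if_noisy,
                 tac_noisy = tac_noisy, noise = noise, seed = seed),
            class = "fdg_scan")
}

#' @export
print.fdg_scan <- function(x, ...) {
  cat(sprintf(paste0("Synthetic FDG scan (seed %d): %g-s protocol, ",
                     "%d frames, %d noisy TAC replicates\n"),
              x$seed, x$protocol$duration, nrow(x$schedule),
              length(x$tac_noisy)))
  print(x$truth)
  invisible(x)
}

#' Write a synthetic scan to a directory
#'
#' Writes the curves as CSV files plus a JSON manifest recording the truth
#' parameters, protocol, noise model and seed.
#'
#' @param scan an `"fdg_scan"` from [make_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(scan, dir) {
  stopifnot(inherits(scan, "fdg_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_curve(scan$plasma, file.path(dir, "plasma.csv"))
  write_curve(scan$blood, file.path(dir, "blood.csv"))
  write_curve(scan$tac, file.path(dir, "tac.csv"))
  for (i in seq_along(scan$tac_noisy))
    write_curve(scan$tac_noisy[[i]], file.path(dir, sprintf("tac_noisy_%02d.csv", i)))
  write_curve(scan$if_noisy, file.path(dir, "plasma_noisy.csv"))
  manifest <- list(seed = scan$seed,
                   protocol = unclass(scan$protocol),
                   truth = as.list(unclass(scan$truth)),
                   triexp = unclass(scan$triexp),
                   noise = unclass(scan$noise))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
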