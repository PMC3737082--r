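# Sensitivity studies for FDG kinetic modeling, scripted and reproducible
# error analyses: each is a pure function of (scans, config) returning a tidy
# data frame with one row per scan x condition (x replicate).

as_scan_list <- function(scans) {
  if (inherits(scans, "fdg_scan")) list(scans)
  else if (is.list(scans) && all(vapply(scans, inherits, TRUE, "fdg_scan"))) scans
  else stop("'scans' must be an fdg_scan or a list of them")
}

scan_id <- function(scans) vapply(scans, function(s) s$seed, numeric(1))

param_row <- function(fit) {
  data.frame(K1 = fit$params[["K1"]], k2 = fit$params[["k2"]],
             k3 = fit$params[["k3"]], k4 = fit$params[["k4"]],
             vb = fit$params[["vb"]], kfdg = fit$kfdg,
             chi2 = fit$chi2, objective = fit$objective,
             converged = fit$converged)
}

#' Fractional-blood-volume sweep
#'
#' For each scan, refits the model with `vb` fixed at each grid value
#' (default 0 to 0.20 in 0.5% steps) and once with `vb` free, on the
#' noise-free TAC. CMRglc per scan is normalized to its mean over the grid
#' so the blood-volume dependence is comparable across scans.
#'
#' @param scans an `"fdg_scan"` or list of them (see [make_fixture()]).
#' @param vb_grid grid of fixed fractional blood volumes.
#' @param glucose plasma glucose (mmol/L) for CMRglc; default 11.9.
#' @param lc lumped constant; default 0.6.
#' @param ... passed to [fit_fdg2tc()] (e.g. `multistart`, `fit_k4`).
#' @return Data frame with one row per scan and grid value (plus a
#'   `vb_free` row per scan flagged in `arm`), including `cmrglc_norm`;
#'   attribute `best_vb` gives the chi-squared-minimizing grid value per
#'   scan.
#' @export
vb_sweep_study <- function(scans, vb_grid = seq(0, 0.2, by = 0.005),
                           glucose = 11.9, lc = 0.6, ...) {
  scans <- as_scan_list(scans)
  out <- NULL
  best <- numeric(0)
  for (s in scans) {
    prof <- vb_profile(s$tac, s$plasma, s$blood, vb_grid = vb_grid, ...)
    cmr <- cmr_glc(prof$kfdg, glucose = glucose, lc = lc)
    rows <- data.frame(scan = s$seed, arm = "grid", prof,
                       cmrglc = cmr, cmrglc_norm = cmr / mean(cmr))
    ffree <- fit_fdg2tc(s$tac, s$plasma, s$blood, fit_vb = TRUE, ...)
    frow <- data.frame(scan = s$seed, arm = "vb_free", vb = ffree$params[["vb"]],
                       K1 = ffree$params[["K1"]], k2 = ffree$params[["k2"]],
                       k3 = ffree$params[["k3"]], k4 = ffree$params[["k4"]],
                       kfdg = ffree$kfdg, chi2 = ffree$chi2,
                       objective = ffree$objective, converged = ffree$converged,
                       cmrglc = cmr_glc(ffree$kfdg, glucose = glucose, lc = lc),
                       cmrglc_norm = NA_real_)
    out <- rbind(out, rows[names(frow)], frow)
    best <- c(best, attr(prof, "best_vb"))
  }
  attr(out, "best_vb") <- stats::setNames(best, scan_id(scans))
  out
}

# shift a sampled curve in time by delta seconds, re-sampled on its own
# grid with constant-end extrapolation
shift_curve <- function(curve, delta) {
  shifted <- stats::approx(curve$time + delta, curve$activity,
                           xout = curve$time, rule = 2)$y
  sampled_curve(curve$time, shifted, kind = attr(curve, "kind"))
}

#' Input-function timing-error study
#'
#' Shifts the input function (and matched blood curve) relative to the TAC
#' by each offset (default -20 to +30 s in 5-s steps), refits at fixed
#' `vb`, and normalizes all parameters to their zero-shift values.
#'
#' @param scans scans, see [vb_sweep_study()].
#' @param shifts time offsets in seconds (positive: IF delayed).
#' @param vb fixed fractional blood volume (default 0.055).
#' @param ... passed to [fit_fdg2tc()].
#' @return Data frame with absolute and normalized (`*_norm`, reference
#'   shift 0 = 1) parameters per scan and shift.
#' @export
time_shift_study <- function(scans, shifts = seq(-20, 30, by = 5),
                             vb = 0.055, ...) {
  scans <- as_scan_list(scans)
  if (!0 %in% shifts) shifts <- sort(c(0, shifts))
  out <- NULL
  for (s in scans) {
    rows <- lapply(shifts, function(d) {
      pl <- if (d == 0) s$plasma else shift_curve(s$plasma, d)
      bl <- if (d == 0) s$blood else shift_curve(s$blood, d)
      f <- fit_fdg2tc(s$tac, pl, bl, vb = vb, ...)
      cbind(data.frame(scan = s$seed, shift = d), param_row(f))
    })
    rows <- do.call(rbind, rows)
    ref <- rows[rows$shift == 0, ]
    for (p in c("K1", "k2", "k3", "kfdg"))
      rows[[paste0(p, "_norm")]] <- rows[[p]] / ref[[p]]
    out <- rbind(out, rows)
  }
  out
}

#' Scanner/counter calibration-error study
#'
#' Multiplies the TAC by each calibration factor (default 0.95 and 1.05),
#' refits, and reports parameters relative to the unmodified fit.
#'
#' @param scans scans, see [vb_sweep_study()].
#' @param factors multiplicative calibration factors applied to the TAC.
#' @param vb fixed fractional blood volume.
#' @param ... passed to [fit_fdg2tc()].
#' @return Data frame with `*_rel` columns (factor 1 row = 1).
#' @export
calibration_study <- function(scans, factors = c(0.95, 1.05), vb = 0.055,
                              ...) {
  scans <- as_scan_list(scans)
  if (!1 %in% factors) factors <- sort(c(1, factors))
  out <- NULL
  for (s in scans) {
    rows <- lapply(factors, function(fc) {
      tac <- frame_tac(s$tac$start, s$tac$end, s$tac$activity * fc,
                       allow_gaps = TRUE)
      f <- fit_fdg2tc(tac, s$plasma, s$blood, vb = vb, ...)
      cbind(data.frame(scan = s$seed, factor = fc), param_row(f))
    })
    rows <- do.call(rbind, rows)
    ref <- rows[rows$factor == 1, ]
    for (p in c("K1", "k2", "k3", "kfdg"))
      rows[[paste0(p, "_rel")]] <- rows[[p]] / ref[[p]]
    out <- rbind(out, rows)
  }
  out
}

# LOWESS smoothing of a sampled curve / frame TAC (robust, MATLAB
# rlowess-like: span as fraction of points, 2 robustifying iterations)
smooth_curve <- function(curve, span = 0.1, iter = 2) {
  sm <- stats::lowess(curve$time, curve$activity, f = span, iter = iter)
  sampled_curve(curve$time, sm$y, kind = attr(curve, "kind"))
}

smooth_tac <- function(tac, span = 0.1, iter = 2) {
  mid <- (tac$start + tac$end) / 2
  sm <- stats::lowess(mid, tac$activity, f = span, iter = iter)
  frame_tac(tac$start, tac$end, sm$y, allow_gaps = TRUE)
}

# delete every second frame (keep 1st, 3rd, ...) to halve the degrees of
# freedom; the result is a gapped schedule
halve_tac <- function(tac) {
  keep <- seq(1, nrow(tac), by = 2)
  frame_tac(tac$start[keep], tac$end[keep], tac$activity[keep],
            allow_gaps = TRUE)
}

#' Data-smoothing study
#'
#' Five data-treatment arms per scan and replicate: unmodified IF with
#' (1) unmodified TAC, (2) TAC with every second frame deleted,
#' (3) LOWESS-smoothed TAC; and LOWESS-smoothed IF with (4) unmodified TAC
#' and (5) smoothed TAC. Fits run on the noisy TAC replicates (and the
#' noisy IF), so the comparison reflects what smoothing does to real,
#' noisy data; paired t-tests against the unmodified arm (Bonferroni
#' corrected) are attached as the `"tests"` attribute.
#'
#' @param scans scans with noisy replicates, see [make_fixture()].
#' @param span LOWESS span (fraction of points; default 0.1).
#' @param iter robustifying iterations (default 2).
#' @param vb fixed fractional blood volume.
#' @param m_bonferroni number of comparisons for the Bonferroni correction
#'   (default: 4 arms x 3 rate constants = 12).
#' @param ... passed to [fit_fdg2tc()].
#' @return Data frame of fits per scan x arm x replicate; attribute
#'   `"tests"` holds the paired-test table.
#' @export
smoothing_study <- function(scans, span = 0.1, iter = 2, vb = 0.055,
                            m_bonferroni = 12L, ...) {
  scans <- as_scan_list(scans)
  out <- NULL
  for (s in scans) {
    if_sm <- smooth_curve(s$if_noisy, span, iter)
    arms <- list(
      full = function(tac) list(tac = tac, pl = s$if_noisy),
      tac_half = function(tac) list(tac = halve_tac(tac), pl = s$if_noisy),
      tac_smooth = function(tac) list(tac = smooth_tac(tac, span, iter),
                                      pl = s$if_noisy),
      if_smooth = function(tac) list(tac = tac, pl = if_sm),
      both_smooth = function(tac) list(tac = smooth_tac(tac, span, iter),
                                       pl = if_sm))
    for (r in seq_along(s$tac_noisy)) {
      for (a in names(arms)) {
        d <- arms[[a]](s$tac_noisy[[r]])
        bl <- blood_from_plasma(d$pl, "mouse_exp")
        f <- fit_fdg2tc(d$tac, d$pl, bl, vb = vb, ...)
        out <- rbind(out, cbind(data.frame(scan = s$seed, arm = a,
                                           replicate = r), param_row(f)))
      }
    }
  }
  tests <- NULL
  for (a in setdiff(unique(out$arm), "full")) {
    for (p in c("K1", "k2", "k3")) {
      x <- out[[p]][out$arm == a]
      y <- out[[p]][out$arm == "full"]
      tt <- stats::t.test(x, y, paired = TRUE)
      tests <- rbind(tests, data.frame(
        arm = a, param = p, mean_ratio = mean(x) / mean(y),
        p_value = tt$p.value,
        p_bonferroni = min(1, tt$p.value * m_bonferroni)))
    }
  }
  attr(out, "tests") <- tests
  out
}

#' Blood-cell-uptake correction study
#'
#' Derives the input function from each scan's whole-blood curve with all
#' four plasma/blood conventions (see [plasma_to_blood_ratio()]), refits,
#' and reports parameters relative to the mouse-correction reference.
#'
#' @param scans scans, see [vb_sweep_study()].
#' @param vb fixed fractional blood volume.
#' @param ... passed to [fit_fdg2tc()].
#' @return Data frame per scan x method with `*_rel` columns
#'   (`mouse_exp` = 1).
#' @export
blood_correction_study <- function(scans, vb = 0.055, ...) {
  scans <- as_scan_list(scans)
  out <- NULL
  for (s in scans) {
    rows <- lapply(.blood_methods, function(m) {
      pl <- plasma_from_blood(s$blood, m)
      f <- fit_fdg2tc(s$tac, pl, s$blood, vb = vb, ...)
      cbind(data.frame(scan = s$seed, method = m), param_row(f))
    })
    rows <- do.call(rbind, rows)
    ref <- rows[rows$method == "mouse_exp", ]
    for (p in c("K1", "k2", "k3", "kfdg"))
      rows[[paste0(p, "_rel")]] <- rows[[p]] / ref[[p]]
    out <- rbind(out, rows)
  }
  out
}

#' Administration-protocol and sampling-interval study
#'
#' For each scan, protocol (default 10-s bolus, 300-s and 900-s infusion)
#' and blood sampling interval (default 1, 30, 60 s): rescales the scan's
#' input function to the protocol at equal dose, regenerates the noise-free
#' TAC from the true parameters on a protocol-specific frame schedule,
#' adds one noisy IF and `n_rep` noisy TAC replicates, subsamples the noisy
#' IF to the sampling interval, and refits each replicate. Fits estimate
#' `k4` by default, as kinetic modeling tools conventionally do (the
#' generator's true `k4` is zero; with coarse
#' bolus sampling the freed `k4` participates in the compensation that
#' inflates the other constants).
#'
#' @param scans scans, see [make_fixture()].
#' @param protocols bolus/infusion durations in seconds.
#' @param intervals blood sampling intervals in seconds.
#' @param n_rep noisy TAC replicates per cell.
#' @param vb fixed fractional blood volume.
#' @param fit_k4 estimate `k4` (default `TRUE`).
#' @param ... passed to [fit_fdg2tc()].
#' @return Data frame per scan x protocol x interval x replicate with
#'   truth-relative columns `*_vs_truth`; attribute `"summary"` holds
#'   per-cell means and SDs.
#' @export
protocol_sampling_study <- function(scans, protocols = c(10, 300, 900),
                                    intervals = c(1, 30, 60), n_rep = 10L,
                                    vb = 0.055, fit_k4 = TRUE, ...) {
  scans <- as_scan_list(scans)
  out <- NULL
  for (s in scans) {
    for (pr in protocols) {
      proto <- protocol_spec(pr, s$protocol$scan_length)
      plasma <- simulate_if(s$triexp, proto)
      blood <- blood_from_plasma(plasma, "mouse_exp")
      schedule <- make_frame_schedule(proto)
      tac0 <- model_tac(s$truth, plasma, blood, schedule)
      base_seed <- s$seed * 10000L + as.integer(pr)
      if_noisy <- add_if_noise(plasma, noise_spec(
        s$noise$if_const_sd, s$noise$if_rel_sd, s$noise$tac_factor,
        seed = base_seed))
      for (iv in intervals) {
        pl <- if (iv <= 1) if_noisy else subsample_if(if_noisy, iv)
        for (r in seq_len(n_rep)) {
          tac <- add_tac_noise(tac0, noise_spec(
            s$noise$if_const_sd, s$noise$if_rel_sd, s$noise$tac_factor,
            seed = base_seed + r))
          f <- fit_fdg2tc(tac, pl, blood, vb = vb, fit_k4 = fit_k4, ...)
          row <- cbind(data.frame(scan = s$seed, protocol = pr,
                                  interval = iv, replicate = r),
                       param_row(f))
          row$K1_vs_truth <- row$K1 / s$truth[["K1"]]
          row$k2_vs_truth <- row$k2 / s$truth[["k2"]]
          row$k3_vs_truth <- row$k3 / s$truth[["k3"]]
          row$kfdg_vs_truth <- row$kfdg / k_fdg(s$truth)
          out <- rbind(out, row)
        }
      }
    }
  }
  agg <- stats::aggregate(out[c("K1", "k2", "k3", "kfdg")],
                          by = out[c("scan", "protocol", "interval")],
                          FUN = mean)
  sds <- stats::aggregate(out[c("K1", "k2", "k3", "kfdg")],
                          by = out[c("scan", "protocol", "interval")],
                          FUN = stats::sd)
  names(sds)[-(1:3)] <- paste0(names(sds)[-(1:3)], "_sd")
  attr(out, "summary") <- merge(agg, sds, by = c("scan", "protocol", "interval"))
  out
}

#' K1/k2 identifiability trade-off
#'
#' Demonstrates how infusion prolongation makes K1 and k2 indistinguishable:
#' starting from a base parameter set (irreversible model), K1 is raised by
#' a factor (default 1.1) and the single multiplier on k2 that best matches
#' the perturbed noise-free TAC back to the original is found by 1-D least
#' squares over the frame values. The residual profile between the two
#' matched TACs concentrates around the infusion stop and shrinks as the
#' infusion lengthens.
#'
#' @param base a [kinetic_params()] with `k4 = 0`.
#' @param triexp input-function description, a [triexp_if()]; default the
#'   canonical fixture IF.
#' @param protocol a [protocol_spec()] or duration in seconds (default
#'   300).
#' @param k1_factor multiplicative perturbation on K1.
#' @param search search interval for the k2 multiplier.
#' @return List with `k2_factor` (the SSD minimizer), `k2_factor_closed_form`
#'   (`(c (k2 + k3) - k3) / k2`, the multiplier preserving the net uptake
#'   rate constant), `ssd`, `residual` (data frame of frame midtime and
#'   matched-TAC difference), `max_residual_time`.
#' @export
k1_k2_tradeoff <- function(base, triexp = canonical_triexp(),
                           protocol = 300, k1_factor = 1.1,
                           search = c(0.8, 1.5)) {
  base <- as_kinetic_params(base)
  if (base[["k4"]] != 0) stop("the trade-off analysis assumes k4 = 0")
  pr <- as_protocol(protocol)
  plasma <- simulate_if(triexp, pr)
  schedule <- make_frame_schedule(pr)
  eng <- tac_engine(plasma, NULL, schedule, dt = 1, blend = "scale")
  p0 <- c(K1 = base[["K1"]], k2 = base[["k2"]], k3 = base[["k3"]],
          k4 = 0, vb = 0)
  y0 <- eng$eval_frames(p0)
  pert <- function(f2) {
    p <- p0
    p["K1"] <- p0[["K1"]] * k1_factor
    p["k2"] <- p0[["k2"]] * f2
    eng$eval_frames(p)
  }
  ssd <- function(f2) { d <- pert(f2) - y0; sum(d * d) }
  opt <- stats::optimize(ssd, search, tol = 1e-8)
  resid <- pert(opt$minimum) - y0
  mid <- (schedule$start + schedule$end) / 2
  cf <- (k1_factor * (base[["k2"]] + base[["k3"]]) - base[["k3"]]) / base[["k2"]]
  list(k2_factor = opt$minimum, k2_factor_closed_form = cf,
       ssd = opt$objective,
       residual = data.frame(time = mid, residual = resid),
       max_residual_time = mid[which.max(abs(resid))])
}
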