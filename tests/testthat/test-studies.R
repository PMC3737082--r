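# Study functions run here on a single fixture scan with reduced
# multistart; the fuller configurations back the acceptance checks.

test_that("K1/k2 trade-off: identity, closed form, and residual location", {
  base <- kinetic_params(0.328, 0.550, 0.079, 0)
  # no perturbation, no compensation
  tr0 <- k1_k2_tradeoff(base, k1_factor = 1)
  expect_equal(tr0$k2_factor, 1, tolerance = 1e-4)
  # closed form preserving K(FDG): (c (k2+k3) - k3) / k2
  tr <- k1_k2_tradeoff(base, k1_factor = 1.1)
  expect_equal(tr$k2_factor_closed_form, 1.114364, tolerance = 1e-5)
  # the SSD minimizer sits near the closed-form value
  expect_equal(tr$k2_factor, tr$k2_factor_closed_form, tolerance = 0.02)
  # the irreducible residual concentrates around the infusion stop
  expect_lt(abs(tr$max_residual_time - 300), 200)
  expect_error(k1_k2_tradeoff(kinetic_params(0.3, 0.5, 0.08, 0.01)),
               "k4 = 0")
})

test_that("calibration errors are absorbed by K1", {
  fx <- scan_noise_free()
  cs <- calibration_study(fx, factors = c(0.95, 1.05), vb = 0,
                          fit_k4 = FALSE, multistart = 2)
  ref <- cs[cs$factor == 1, ]
  expect_equal(ref$K1_rel, 1)
  for (fc in c(0.95, 1.05)) {
    row <- cs[cs$factor == fc, ]
    expect_equal(row$K1_rel, fc, tolerance = 1e-3)
    expect_equal(row$k2_rel, 1, tolerance = 1e-3)
    expect_equal(row$k3_rel, 1, tolerance = 1e-3)
  }
  # with the finite blood volume the compensation is no longer exact but
  # still lands dominantly on K1
  cs2 <- calibration_study(fx, factors = 1.05, vb = 0.055,
                           fit_k4 = FALSE, multistart = 2)
  row <- cs2[cs2$factor == 1.05, ]
  expect_equal(row$K1_rel, 1.05, tolerance = 0.03)
  expect_lt(abs(row$k2_rel - 1), abs(row$K1_rel - 1))
  expect_lt(abs(row$k3_rel - 1), abs(row$K1_rel - 1))
})

test_that("timing errors degrade the fit away from zero shift", {
  fx <- scan_noise_free()
  ts <- time_shift_study(fx, shifts = seq(-20, 30, by = 10),
                         fit_k4 = FALSE, multistart = 2)
  z <- ts[ts$shift == 0, ]
  expect_equal(z$K1_norm, 1)
  expect_equal(z$k2_norm, 1)
  expect_equal(which.min(ts$chi2), which(ts$shift == 0))
  # a 20-s timing error distorts at least one rate constant by >= 20%
  s20 <- ts[abs(ts$shift) == 20, ]
  expect_true(any(abs(as.matrix(s20[, c("K1_norm", "k2_norm", "k3_norm")]) - 1)
                  >= 0.20))
})

test_that("blood-cell correction choice shifts the transport estimates", {
  fx <- scan_noise_free()
  bc <- blood_correction_study(fx, fit_k4 = FALSE, multistart = 2)
  wb <- bc[bc$method == "whole_blood", ]
  rat <- bc[bc$method == "rat_biexp", ]
  cs <- bc[bc$method == "constant_scale", ]
  # whole-blood input function overestimates K1
  expect_gt(wb$K1_rel, 1.05)
  # mouse and rat corrections agree far better than whole blood deviates
  expect_lt(max(abs(c(rat$K1_rel, rat$k2_rel, rat$k3_rel) - 1)),
            abs(wb$K1_rel - 1))
  # constant scaling keeps the uptake constant within ~20% of reference
  expect_lt(abs(cs$kfdg_rel - 1), 0.2)
})

test_that("vb sweep: goodness of fit and transport-parameter direction", {
  fx <- scan_noise_free()
  vs <- vb_sweep_study(fx, vb_grid = seq(0.035, 0.075, by = 0.01),
                       fit_k4 = FALSE, multistart = 1)
  g <- vs[vs$arm == "grid", ]
  expect_equal(g$vb[which.min(g$chi2)], 0.055)
  # transport parameters fall monotonically with assumed blood volume
  expect_true(all(diff(g$K1) < 0))
  expect_true(all(diff(g$k2) < 0))
  # normalized CMRglc is ~1 at the generating vb
  expect_equal(g$cmrglc_norm[which.min(abs(g$vb - 0.055))], 1,
               tolerance = 0.02)
  # the free fit recovers the generating vb on clean data
  expect_equal(vs$vb[vs$arm == "vb_free"], 0.055, tolerance = 0.01)
})

test_that("smoothing alters rate-constant estimates on noisy data", {
  fx <- scan_noisy()
  sm <- smoothing_study(fx, fit_k4 = FALSE, multistart = 2)
  # the deletion arm halves the TAC length (rounding up)
  n_full <- sum(sm$arm == "full")
  expect_equal(nrow(fx$schedule) %/% 2 + nrow(fx$schedule) %% 2,
               nrow(fdgkin:::halve_tac(fx$tac)))
  tests <- attr(sm, "tests")
  # smoothing the input function biases the estimates detectably
  ps <- tests$p_bonferroni[tests$arm %in% c("if_smooth", "both_smooth")]
  expect_true(any(ps < 0.05))
  expect_equal(n_full, length(fx$tac_noisy))

  # smoothing an already noise-free curve barely moves the fit
  f0 <- fit_fdg2tc(fx$tac, fx$plasma, fx$blood, fit_k4 = FALSE,
                   multistart = 2)
  f1 <- fit_fdg2tc(fdgkin:::smooth_tac(fx$tac), fx$plasma, fx$blood,
                   fit_k4 = FALSE, multistart = 2)
  expect_lt(max(abs(coef(f1)[c("K1", "k2", "k3")] /
                      coef(f0)[c("K1", "k2", "k3")] - 1)), 0.05)
})

test_that("study tables are reproducible functions of seed and config", {
  fx <- make_fixture(seed = 3, n_rep = 2)
  a <- calibration_study(fx, factors = 1.05, fit_k4 = FALSE, multistart = 1)
  b <- calibration_study(make_fixture(seed = 3, n_rep = 2), factors = 1.05,
                         fit_k4 = FALSE, multistart = 1)
  expect_identical(a, b)
})
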