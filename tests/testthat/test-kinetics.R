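test_that("impulse response has the closed-form rates and amplitudes", {
  # degenerate uptake-only case: pure integrator
  ir <- impulse_response(kinetic_params(1, 0, 0, 0))
  expect_equal(ir$rates, 0)
  expect_equal(ir$amps, 1)

  # irreversible parameters: slow rate exactly zero, fast rate k2 + k3,
  # trapped amplitude K1 k3 / (k2 + k3)  (hand algebra on the 2TC solution)
  ir <- impulse_response(kinetic_params(0.328, 0.550, 0.079, 0))
  expect_equal(ir$rates[1], 0)
  expect_equal(ir$rates[2], 0.629)
  expect_equal(ir$amps[1], 0.328 * 0.079 / 0.629, tolerance = 1e-12)
  expect_equal(sum(ir$amps), 0.328)

  # k4 = 0 always gives a non-decaying component; amplitudes sum to K1
  for (i in 1:20) {
    set.seed(i)
    p <- kinetic_params(runif(1, 0.05, 1), runif(1, 0.1, 1),
                        runif(1, 0.01, 0.3), 0)
    ir <- impulse_response(p)
    expect_equal(ir$rates[1], 0)
    expect_equal(sum(ir$amps), p[["K1"]])
  }

  # reversible: both rates positive, ordered
  ir <- impulse_response(kinetic_params(0.3, 0.5, 0.08, 0.02))
  expect_true(ir$rates[1] > 0 && ir$rates[1] < ir$rates[2])
  expect_equal(sum(ir$amps), 0.3)

  expect_error(kinetic_params(-0.1, 0.5, 0.08), "non-negative")
})

test_that("K(FDG) and CMRglc follow their defining formulas", {
  # published rate-constant sets reproduce the published uptake constants
  expect_equal(round(k_fdg(0.156, 0.329, 0.032), 3), 0.014)
  expect_equal(k_fdg(0.328, 0.550, 0.079), 0.0412, tolerance = 1e-3)
  expect_equal(k_fdg(1, 1, 0), 0)
  expect_error(k_fdg(1, 0, 0), "undefined")

  # K(FDG) <= K1 for arbitrary non-negative constants
  for (i in 1:50) {
    set.seed(i)
    K1 <- runif(1, 0, 2)
    expect_lte(k_fdg(K1, runif(1, 0, 2), runif(1, 0, 2)), K1)
  }

  expect_equal(cmr_glc(0.030, glucose = 10, lc = 0.6), 50)
  expect_equal(cmr_glc(0.0412, glucose = 11.9, lc = 0.6), 81.7,
               tolerance = 1e-3)
  expect_equal(cmr_glc(0.05, glucose = 0), 0)
  expect_error(cmr_glc(0.05, glucose = 10, lc = 0), "positive")
})

test_that("model TAC degenerates correctly at the edges", {
  fx <- scan_noise_free()
  # vb = 1: the measured signal is the frame-averaged blood curve
  p <- kinetic_params(0.3, 0.5, 0.08, 0.01, vb = 1)
  mt <- model_tac(p, fx$plasma, fx$blood, fx$schedule)
  bl_frames <- frame_means_1s(fx$blood$activity, fx$schedule$start,
                              fx$schedule$end)
  expect_equal(mt$activity, bl_frames, tolerance = 1e-10)

  # K1 = 0 and vb = 0: no signal at all
  mt0 <- model_tac(kinetic_params(0, 0.5, 0.08, 0, vb = 0), fx$plasma,
                   fx$blood, fx$schedule)
  expect_true(all(mt0$activity == 0))

  # additive blending differs from the rescaling convention by the
  # (1 - vb) factor on the tissue term
  psm <- kinetic_params(0.3, 0.5, 0.08, 0, vb = 0.055)
  m_scale <- model_tac(psm, fx$plasma, fx$blood, fx$schedule, blend = "scale")
  m_add <- model_tac(psm, fx$plasma, fx$blood, fx$schedule, blend = "add")
  tissue <- model_tac(kinetic_params(0.3, 0.5, 0.08, 0, vb = 0), fx$plasma,
                      fx$blood, fx$schedule)
  expect_equal(m_add$activity - m_scale$activity, 0.055 * tissue$activity,
               tolerance = 1e-9)

  expect_error(model_tac(psm, fx$plasma, NULL, fx$schedule), "blood curve")
})

test_that("model TAC is linear in K1 at vb = 0", {
  fx <- scan_noise_free()
  base <- model_tac(kinetic_params(0.25, 0.5, 0.08, 0.01, vb = 0),
                    fx$plasma, NULL, fx$schedule)
  for (c in c(0.5, 2, 3.7)) {
    scaled <- model_tac(kinetic_params(c * 0.25, 0.5, 0.08, 0.01, vb = 0),
                        fx$plasma, NULL, fx$schedule)
    expect_equal(scaled$activity, c * base$activity, tolerance = 1e-12)
  }
})

test_that("model TAC matches a brute-force ODE integration to <0.1%", {
  fx <- scan_noise_free()
  sched <- fx$schedule
  set.seed(7)
  for (i in 1:20) {
    p <- kinetic_params(runif(1, 0.1, 0.6), runif(1, 0.2, 1),
                        runif(1, 0.02, 0.2), runif(1, 0, 0.05), vb = 0)
    mt <- model_tac(p, fx$plasma, NULL, sched)
    ode <- rk4_tissue(p[["K1"]], p[["k2"]], p[["k3"]], p[["k4"]], fx$plasma)
    ode_frames <- frame_means_1s(ode, sched$start, sched$end)
    expect_lt(max(abs(mt$activity - ode_frames) / pmax(ode_frames, 1e-12)),
              0.001)
  }
})

test_that("late Patlak slope equals K(FDG) for irreversible kinetics", {
  # independent graphical-method cross-check on a decaying input function
  tri <- triexp_if(500, 400, 300, 3, 0.3, 0.08, 300)
  pl <- simulate_if(tri, protocol_spec(300, 5400))
  p <- kinetic_params(0.3, 0.5, 0.08, 0)
  sched <- frame_tac(seq(0, 5300, 100), seq(100, 5400, 100))
  mt <- model_tac(p, pl, NULL, sched)
  cp <- pl$activity
  icp <- cumsum((cp[-1] + cp[-length(cp)]) / 2)  # running integral, 1-s steps
  mid <- (sched$start + sched$end) / 2
  cpm <- approx(pl$time, cp, mid)$y
  x <- approx(pl$time[-1], icp, mid)$y / cpm / 60  # minutes
  y <- mt$activity / cpm
  late <- mid > 3000
  slope <- coef(lm(y[late] ~ x[late]))[[2]]
  expect_equal(slope, k_fdg(p), tolerance = 1e-4)
})
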