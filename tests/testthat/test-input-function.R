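test_that("plasma/blood ratio functions match their printed coefficients", {
  # t = 0 values are sums of the printed coefficients
  expect_equal(plasma_to_blood_ratio(0, "mouse_exp"), 0.386 + 1.165)
  expect_equal(plasma_to_blood_ratio(0, "rat_biexp"), 0.51 + 0.3 + 0.8)
  # asymptote of the mouse correction: the equilibrium partition coefficient
  expect_equal(plasma_to_blood_ratio(1e9, "mouse_exp"), 1.165)
  expect_equal(plasma_to_blood_ratio(123, "constant_scale"), 1.165)
  expect_equal(plasma_to_blood_ratio(123, "whole_blood"), 1)
  # exponent argument is time in minutes
  expect_equal(plasma_to_blood_ratio(60, "mouse_exp"),
               0.386 * exp(-0.191) + 1.165)
  expect_error(plasma_to_blood_ratio(-1, "mouse_exp"), "non-negative")

  # both exponential corrections decrease strictly and stay above their
  # asymptotes
  tt <- seq(0, 3600, by = 10)
  for (m in c("mouse_exp", "rat_biexp")) {
    r <- plasma_to_blood_ratio(tt, m)
    expect_true(all(diff(r) < 0))
    expect_true(all(r > if (m == "mouse_exp") 1.165 else 0.8))
  }
})

test_that("plasma and blood conversions are exact inverses", {
  bl <- sampled_curve(0:100, 100 + 50 * sin(0:100 / 10), kind = "blood")
  for (m in c("mouse_exp", "rat_biexp", "constant_scale", "whole_blood")) {
    round_trip <- blood_from_plasma(plasma_from_blood(bl, m), m)
    expect_equal(round_trip$activity, bl$activity, tolerance = 1e-12)
  }
  # hand-computed values
  const <- sampled_curve(0:10, rep(100, 11), kind = "blood")
  expect_equal(plasma_from_blood(const, "constant_scale")$activity,
               rep(116.5, 11))
  expect_equal(plasma_from_blood(const, "mouse_exp")$activity[1], 155.1)
})

test_that("tri-exponential curve: endpoints, continuity, fractional areas", {
  p <- canonical_triexp()
  expect_equal(triexp_value(p, 0), 0)
  # extrapolated steady state A + B + Z under unending infusion
  long <- triexp_if(p$A, p$B, p$Z, p$alpha, p$beta, p$zeta, t_i = 1e9)
  expect_equal(triexp_value(long, 1e8), p$A + p$B + p$Z, tolerance = 1e-6)

  # continuity at t_i for random parameter sets
  set.seed(11)
  for (i in 1:50) {
    q <- triexp_if(runif(1, 0, 500), runif(1, 0, 500), runif(1, 0, 5000),
                   runif(1, 1, 5), runif(1, 0.1, 1), runif(1, 0.005, 0.05),
                   t_i = runif(1, 60, 900))
    eps <- 1e-6
    expect_equal(triexp_value(q, q$t_i), triexp_value(q, q$t_i + eps),
                 tolerance = 1e-6)
    f <- fractional_areas(q)
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(sum(f), 1)
    # non-negative, rising during infusion, falling after
    tt <- seq(0, 2700, by = 5)
    v <- triexp_value(q, tt)
    expect_true(all(v >= 0))
    expect_true(all(diff(v[tt <= q$t_i]) > 0))
    expect_true(all(diff(v[tt > q$t_i]) < 0))
  }

  # symmetric parameters share the area equally
  sym <- triexp_if(10, 10, 10, 0.5, 0.5, 0.5, 300)
  expect_equal(unname(fractional_areas(sym)), rep(1 / 3, 3))
  expect_equal(unname(fractional_areas(triexp_if(5, 0, 0, 1, 1, 1, 60))),
               c(1, 0, 0))
})

test_that("protocol rescaling preserves dose and area under the curve", {
  p <- canonical_triexp()
  r900 <- rescale_protocol(p, 900)
  expect_equal(r900$A, p$A / 3)
  expect_equal(r900$Z, p$Z / 3)
  expect_equal(r900$t_i, 900)
  r10 <- rescale_protocol(p, 10)
  expect_equal(r10$B, p$B * 30)
  # infusion rate x duration (total dose) invariant
  expect_equal(r900$A * r900$t_i, p$A * p$t_i)

  # area under the curve out to t >> 1/zeta is protocol-invariant to <0.5%
  tt <- seq(0, 120000, by = 5)
  auc <- function(q) sum(triexp_value(q, tt)) * 5
  expect_equal(auc(r900) / auc(p), 1, tolerance = 0.005)
  expect_equal(auc(r10) / auc(p), 1, tolerance = 0.005)
})

test_that("tri-exponential fit recovers known parameters", {
  tru <- canonical_triexp()
  cur <- simulate_if(tru, 300)
  # automated stop detection finds the true maximum on a clean curve
  expect_equal(detect_infusion_stop(cur), 300)
  ft <- fit_triexp(cur)
  est <- unlist(ft$par)[1:6]
  expect_lt(max(abs(est / unlist(tru)[1:6] - 1)), 0.01)
  expect_lt(ft$rss, 1e-10)
  # fitted curve passes through the empirical maximum at t_i
  expect_equal(triexp_value(ft$par, 300), max(cur$activity), tolerance = 1e-6)
})

test_that("steady-state recovery from noisy input functions", {
  # Monte-Carlo recovery of the extrapolated steady state A+B+Z under the
  # stated IF noise model. The slow component is only ~5% saturated after
  # a 300-s infusion, so the plain unweighted fit recovers S with errors
  # up to ~15%; inverse-variance weighting by the known noise SD brings
  # the mean error within 5%.
  tru <- canonical_triexp()
  cur <- simulate_if(tru, 300)
  S <- tru$A + tru$B + tru$Z
  err <- vapply(1:10, function(s) {
    cn <- add_if_noise(cur, noise_spec(seed = s))
    sd <- 32.5 + 0.05 * pmax(cn$activity, 0)
    f <- fit_triexp(cn, multistart = 2L, seed = s, sd = sd)
    (f$par$A + f$par$B + f$par$Z) / S - 1
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.05)
  expect_lt(max(abs(err)), 0.10)
})
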