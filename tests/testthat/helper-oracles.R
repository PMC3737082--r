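# Independent oracles used across tests.

# Brute-force fixed-step RK4 integration of the two-compartment system
#   dC1/dt = K1 Cp - (k2+k3) C1 + k4 C2 ;  dC2/dt = k3 C1 - k4 C2
# with linear interpolation of the plasma curve. Returns the total tissue
# activity C1 + C2 at every whole second 0..tmax. Deliberately shares no
# code with the package's convolution engine.
rk4_tissue <- function(K1, k2, k3, k4, plasma, dt = 0.1, tmax = 2700) {
  K1 <- K1 / 60; k2 <- k2 / 60; k3 <- k3 / 60; k4 <- k4 / 60
  cpf <- stats::approxfun(plasma$time, plasma$activity, rule = 2)
  n <- round(tmax / dt)
  grid <- seq(0, tmax, by = dt)
  cp_full <- cpf(grid)
  cp_half <- cpf(grid[-length(grid)] + dt / 2)
  c1 <- 0; c2 <- 0
  out <- numeric(tmax + 1)
  deriv <- function(c1, c2, cp) c(K1 * cp - (k2 + k3) * c1 + k4 * c2,
                                  k3 * c1 - k4 * c2)
  for (i in seq_len(n)) {
    a <- deriv(c1, c2, cp_full[i])
    b <- deriv(c1 + dt / 2 * a[1], c2 + dt / 2 * a[2], cp_half[i])
    cc <- deriv(c1 + dt / 2 * b[1], c2 + dt / 2 * b[2], cp_half[i])
    d <- deriv(c1 + dt * cc[1], c2 + dt * cc[2], cp_full[i + 1])
    c1 <- c1 + dt / 6 * (a[1] + 2 * b[1] + 2 * cc[1] + d[1])
    c2 <- c2 + dt / 6 * (a[2] + 2 * b[2] + 2 * cc[2] + d[2])
    tcur <- grid[i + 1]
    if (abs(tcur - round(tcur)) < 1e-9) out[round(tcur) + 1] <- c1 + c2
  }
  out
}

# frame averages of a 1-s instantaneous curve (values at t = 0..tmax),
# independent trapezoid implementation
frame_means_1s <- function(values, start, end) {
  vapply(seq_along(start), function(i) {
    seg <- values[(start[i]:end[i]) + 1]
    (sum(seg) - 0.5 * (seg[1] + seg[length(seg)])) / (end[i] - start[i])
  }, numeric(1))
}

# default noise-free test scan, cached per test run
scan_noise_free <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture(seed = 1, n_rep = 0, jitter = 0)
    cache
  }
})

# default noisy test scan (10 replicates), cached
scan_noisy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture(seed = 1, n_rep = 10, jitter = 0)
    cache
  }
})
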