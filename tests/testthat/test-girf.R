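make_identity_system <- function() {
  synth_gradient_system(delay_per_axis_s = c(x = 0),
                        resonance_freqs_hz = numeric(0),
                        lowpass_cutoff_hz = Inf)
}

test_that("synthetic gradient systems have the prescribed structure", {
  idg <- make_identity_system()
  expect_lt(max(Mod(idg$H - 1)), 1e-12)

  # pure delay: phase slope equals -2 pi tau
  tau <- 3e-6
  dg <- synth_gradient_system(delay_per_axis_s = c(x = tau),
                              resonance_freqs_hz = numeric(0),
                              lowpass_cutoff_hz = Inf)
  expect_equal(unname(girf_delay(dg)["x"]), tau, tolerance = 1e-12)
  f <- dg$freq_hz
  expect_equal(Arg(dg$H[f > 0 & f < 1e4, 1]),
               (-2 * pi * tau * f[f > 0 & f < 1e4]), tolerance = 1e-9)

  # default z system: 2.5 us delay recovered from a simulated measurement
  sys_g <- synth_gradient_system()
  probes <- girf_probe_set()
  meas <- lapply(probes, function(p) thin_slice_measurement(sys_g, p,
                                                            axis = "z"))
  est <- estimate_girf(probes, meas, axis = "z")
  expect_lt(abs(girf_delay(est)["z"] - 2.5e-6), 5e-6)  # raster/2 bound
  expect_lt(abs(girf_delay(est)["z"] - 2.5e-6), 0.2e-6)

  expect_error(synth_gradient_system(lowpass_cutoff_hz = -1), "> 0")
})

test_that("thin-slice measurement recovers the played gradient", {
  idg <- make_identity_system()
  probe <- girf_probe_set(n_probes = 1)[[1]]
  m <- thin_slice_measurement(idg, probe, axis = "x")
  expect_lt(max(abs(m$G[, 1] - probe$G[, 1])), 1e-9)

  # pure delay shows up as a time shift (cross-correlation peak)
  tau <- 40e-6                         # 4 raster steps, resolvable
  dg <- synth_gradient_system(delay_per_axis_s = c(x = tau),
                              resonance_freqs_hz = numeric(0),
                              lowpass_cutoff_hz = Inf)
  md <- thin_slice_measurement(dg, probe, axis = "x")
  cc <- vapply(0:8, function(l) {
    n <- nrow(probe$G)
    sum(probe$G[seq_len(n - l), 1] * md$G[seq_len(n - l) + l, 1])
  }, numeric(1))
  expect_equal(which.max(cc) - 1, tau / probe$dt)

  # slice offset scales out of the recovered gradient (offsets kept small
  # enough that the per-sample phase increment stays below half a cycle)
  m2 <- thin_slice_measurement(idg, probe, slice_offset_m = 0.01, axis = "x")
  expect_lt(max(abs(m2$G[, 1] - m$G[, 1])), 1e-9)

  expect_error(thin_slice_measurement(idg, probe, slice_offset_m = 0),
               "nonzero")
})

test_that("GIRF estimation recovers synthetic systems and averages noise", {
  probes <- girf_probe_set()
  # measured == probes -> H ~= 1 (within regularization bias)
  est_id <- estimate_girf(probes, probes, axis = "x")
  inband <- abs(est_id$freq_hz) < 4e3
  expect_lt(max(Mod(est_id$H[inband, 1] - 1)), 0.01)

  # full round trip on a held-out waveform, in-band RMS < 1%
  sys_g <- synth_gradient_system()
  meas <- lapply(probes, function(p) thin_slice_measurement(sys_g, p,
                                                            axis = "y"))
  est <- estimate_girf(probes, meas, axis = "y")
  ro <- build_readout(readout_design(), scheme_preset("bipolar3T"))
  wf <- gradient_waveform(ro$G[, 1], ro$dt, "y")
  g_true <- apply_girf(wf, sys_g)$G[, 1]
  g_est <- apply_girf(wf, est)$G[, 1]
  expect_lt(sqrt(mean((g_true - g_est)^2) / mean(g_true^2)), 0.01)

  # averaging repeated noisy measurements reduces the recovery error
  err_for_reps <- function(n_rep) {
    meas_n <- lapply(seq_along(probes), function(i) {
      acc <- 0
      for (r in seq_len(n_rep)) {
        acc <- acc + thin_slice_measurement(sys_g, probes[[i]],
                                            noise_sd = 0.02,
                                            seed = 1000 * r + i,
                                            axis = "y")$G[, 1]
      }
      gradient_waveform(acc / n_rep, probes[[i]]$dt, "y")
    })
    e <- estimate_girf(probes, meas_n, axis = "y")
    sqrt(mean((apply_girf(wf, e)$G[, 1] - g_true)^2))
  }
  e1 <- err_for_reps(1); e8 <- err_for_reps(8)
  expect_lt(e8, e1)
})

test_that("apply_girf identity, delay and linearity", {
  ro <- build_readout(readout_design(), scheme_preset("monopolar3T"))
  wf <- gradient_waveform(ro$G[, 1], ro$dt, "x")
  idg <- make_identity_system()
  expect_equal(apply_girf(wf, idg)$G, wf$G, tolerance = 1e-9)

  # delay of exactly one raster step shifts samples by one (interior)
  dg <- synth_gradient_system(delay_per_axis_s = c(x = wf$dt),
                              resonance_freqs_hz = numeric(0),
                              lowpass_cutoff_hz = Inf)
  shifted <- apply_girf(wf, dg)$G[, 1]
  n <- length(shifted)
  expect_equal(shifted[10:n], wf$G[9:(n - 1), 1], tolerance = 1e-6)

  # linearity
  wf2 <- gradient_waveform(rev(ro$G[, 1]), ro$dt, "x")
  sys_g <- synth_gradient_system()
  lhs <- apply_girf(gradient_waveform(2 * wf$G[, 1] - 3 * wf2$G[, 1], wf$dt,
                                      "x"), sys_g)$G
  rhs <- 2 * apply_girf(wf, sys_g)$G - 3 * apply_girf(wf2, sys_g)$G
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("trajectory integration closed forms and parity shifts", {
  sys3t <- system_config()
  dt <- 10e-6
  # constant G over T: k(T) = gamma G T (in grid units: x FOV)
  G <- 10  # mT/m
  wf <- gradient_waveform(rep(G, 101), dt, "x")
  traj <- integrate_trajectory(wf, sys3t, fov_m = 0.22)
  k_expect <- sys3t$gamma_hz_per_t * G * 1e-3 * (100 * dt) * 0.22
  expect_equal(unname(traj$k[101, 1]), k_expect, tolerance = 1e-9)

  # balanced bipolar lobe pair returns to k = 0
  lobe <- c(seq(0, 10, length.out = 6), rep(10, 20), seq(10, 0,
                                                         length.out = 6))
  bal <- gradient_waveform(c(lobe, -lobe), dt, "x")
  tb <- integrate_trajectory(bal, sys3t, fov_m = 0.22)
  expect_lt(abs(tb$k[nrow(tb$k), 1]), 1e-9)

  # delayed plateau: echo-center k shift = gamma G tau (grid units)
  tau <- 20e-6
  base <- c(rep(0, 20), rep(G, 200), rep(0, 20))
  nomi <- integrate_trajectory(gradient_waveform(base, dt, "x"), sys3t, 0.22,
                               echo_samples = list(120:140))
  dg <- synth_gradient_system(delay_per_axis_s = c(x = tau),
                              resonance_freqs_hz = numeric(0),
                              lowpass_cutoff_hz = Inf)
  del <- integrate_trajectory(apply_girf(gradient_waveform(base, dt, "x"),
                                         dg), sys3t, 0.22,
                              echo_samples = list(120:140))
  shift <- mean(del$k[120:140, 1] - nomi$k[120:140, 1])
  expect_equal(shift, -sys3t$gamma_hz_per_t * G * 1e-3 * tau * 0.22,
               tolerance = 0.02)

  # parity aggregation: trivial cases
  nomi$echo_samples <- list(1:60, 61:120, 121:180, 181:240)
  nomi$echo_parity <- c("odd", "even", "odd", "even")
  same <- nomi
  expect_equal(echo_parity_shift(nomi, same), c(even = 0, odd = 0))
  shifted <- nomi
  shifted$k[c(61:120, 181:240), 1] <- shifted$k[c(61:120, 181:240), 1] + 1
  ps <- echo_parity_shift(nomi, shifted)
  expect_equal(unname(ps["even"]), 1, tolerance = 1e-9)
  expect_equal(unname(ps["odd"]), 0, tolerance = 1e-9)
  bad <- nomi; bad$k <- bad$k[1:10, , drop = FALSE]
  expect_error(echo_parity_shift(nomi, bad), "congruent")
})
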