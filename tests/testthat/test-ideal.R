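test_that("varpro fit recovers noiseless generation parameters", {
  sp <- default_fat_spectrum()
  te <- echo_times(scheme_preset("bipolar3T"))
  y <- fixture_voxel_signal(W = 0.7, F = 0.3, f0 = 40, r2s = 50)
  fit <- varpro_fit_voxel(y, te, sp)
  expect_equal(Mod(fit$W), 0.7, tolerance = 1e-3)
  expect_equal(Mod(fit$F), 0.3, tolerance = 1e-3)
  expect_equal(fit$f0, 40, tolerance = 0.5)
  expect_equal(fit$r2star, 50, tolerance = 0.5)
  expect_equal(fit$pdff, 30, tolerance = 0.1)
  # residual of the projection at the true parameters is numerically zero
  at_truth <- oracle_varpro(y, te, sp$shifts_ppm, sp$rel_amplitudes,
                            f0_grid = 40, r2s_grid = 50)
  expect_lt(sqrt(at_truth$res), 1e-10 * sqrt(sum(Mod(y)^2)))
  # the common initial phase is absorbed into the complex amplitudes
  expect_equal(Arg(fit$W) * 180 / pi, 30, tolerance = 0.5)

  # degenerate all-zero voxel
  z <- varpro_fit_voxel(complex(13), te, sp)
  expect_true(z$degenerate)
  expect_equal(z$residual, 0)
  expect_equal(z$pdff, 0)

  # pure fat
  yf <- fixture_voxel_signal(W = 0, F = 1, f0 = 0, r2s = 50)
  expect_equal(varpro_fit_voxel(yf, te, sp)$pdff, 100, tolerance = 0.1)

  expect_error(varpro_fit_voxel(y[1:3], te[1:3], sp), "4 echoes")
  expect_error(varpro_fit_voxel(c(y[-1], NaN + 0i), te, sp), "finite")
})

test_that("grid+refine matches the exhaustive brute-force oracle", {
  sp <- fat_spectrum(c(-3.4, -2.5, 0.6), c(0.7, 0.2, 0.1))
  te <- echo_times(scheme_preset("bipolar3T"))
  cfg <- fit_config()
  set.seed(11)
  n_cases <- 25
  for (i in seq_len(n_cases)) {
    W <- runif(1, 0.1, 1); F <- runif(1, 0, 1)
    f0 <- runif(1, -180, 180); r2s <- runif(1, 5, 150)
    y <- simulate_signal(tissue_voxel(W, F, 30, f0, r2s), sp, te)
    fit <- varpro_fit_voxel(y, te, sp, cfg)
    orc <- oracle_varpro(y, te, sp$shifts_ppm, sp$rel_amplitudes,
                         f0_grid = seq(f0 - 6, f0 + 6, by = 0.25),
                         r2s_grid = seq(max(r2s - 10, 0), r2s + 10, by = 0.25))
    # agreement within one refinement-grid resolution
    expect_lt(abs(fit$f0 - orc$f0), 1)
    expect_lt(abs(fit$r2star - orc$r2s), 2.5)
    expect_lt(abs(Mod(fit$F) / (Mod(fit$W) + Mod(fit$F)) -
                    Mod(orc$F) / (Mod(orc$W) + Mod(orc$F))), 5e-3)
  }
})

test_that("water-fat exchange symmetry with a single-peak basis", {
  sp1 <- fixture_spectrum_single()
  te <- echo_times(scheme_preset("bipolar3T"))
  f_fat <- peak_frequencies(sp1)
  y <- simulate_signal(tissue_voxel(0.8, 0.2, 0, 0, 30), sp1, te)
  p <- varpro_fit_voxel(y, te, sp1)$pdff
  # exchanging the water and fat amplitudes mirrors the estimated fraction
  y2 <- simulate_signal(tissue_voxel(0.2, 0.8, 0, 0, 30), sp1, te)
  expect_equal(varpro_fit_voxel(y2, te, sp1)$pdff, 100 - p, tolerance = 0.5)
  # and the swapped signal itself sits at an off-resonance alias: the same
  # magnitudes with f0 = f_fat fit equally well with labels exchanged
  y3 <- simulate_signal(tissue_voxel(0.2, 0.8, 0, f_fat, 30), sp1, te)
  fit3 <- varpro_fit_voxel(y3, te, sp1)
  expect_true(abs(fit3$pdff - 80) < 0.5 || abs(fit3$pdff - 20) < 0.5)
})

test_that("compute_pdff magnitude discrimination", {
  expect_equal(compute_pdff(1 + 0i, 0i), 0)
  expect_equal(compute_pdff(0i, 1 + 0i), 100)
  expect_equal(compute_pdff(3 + 0i, 0 + 1i), 25)
  expect_equal(compute_pdff(0i, 0i), 0)
  expect_equal(compute_pdff(c(1, 0) + 0i, c(0, 1) + 0i), c(0, 100))
})

test_that("fit_volume is deterministic, masks bad voxels, respects truth", {
  sp <- default_fat_spectrum()
  grid <- silico_grid(pdff_axis = seq(0, 100, 20), f0_axis = c(-60, 0, 60),
                      n_reps = 3)
  vol <- normalize_volume(generate_silico_volume(grid,
                                                 scheme_preset("bipolar3T")))
  res <- fit_volume(vol, sp)
  rep <- accuracy_report(grid, res)
  # noiseless recovery everywhere (100% PDFF has a known ambiguity region)
  expect_lt(max(abs(rep$profiles$bias_pdff[grid$pdff_axis < 100])), 0.1)
  expect_lt(rep$max_abs_err_r2s_over_pdff, 0.5)

  res2 <- fit_volume(vol, sp)
  expect_identical(res$pdff_map, res2$pdff_map)

  # a non-finite voxel is masked, not fatal
  vol$data[2, 2, 2, 5] <- NaN + 0i
  res3 <- fit_volume(vol, sp)
  expect_false(res3$mask[2, 2, 2])
  expect_equal(res3$pdff_map[2, 2, 2], 0)
  expect_true(all(res3$mask[1, , ]))
})

test_that("field-map constraint resolves aliases against neighbors", {
  # two-region field map: a smooth background and a small inner region;
  # with noise, isolated voxels land on aliased f0 minima and the
  # neighborhood constraint pulls them back
  sp <- default_fat_spectrum()
  sch <- scheme_preset("monopolar3T")
  grid <- silico_grid(pdff_axis = seq(10, 60, 10), f0_axis = seq(-40, 40, 10),
                      n_reps = 4, snr = 10)
  vol <- add_complex_noise(normalize_volume(generate_silico_volume(grid, sch)),
                           10, 5)
  res_free <- fit_volume(vol, sp, fit_config(n_local_iters = 0))
  res_con <- fit_volume(vol, sp)
  f0_true <- array(rep(grid$f0_axis, each = 6), dim = c(6, 9, 4))
  frac_free <- mean(abs(res_free$f0_map - f0_true) > 60)
  frac_con <- mean(abs(res_con$f0_map - f0_true) > 60)
  expect_lte(frac_con, frac_free)
  expect_lt(frac_con, 0.02)
})
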