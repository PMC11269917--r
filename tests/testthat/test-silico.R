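test_that("silico volume has the study-grid shape and voxel-wise content", {
  grid <- silico_grid(n_reps = 2)
  vol <- generate_silico_volume(grid, scheme_preset("bipolar3T"))
  expect_equal(dim(vol$data), c(101, 101, 2, 13))

  # default grid arithmetic: 0:1:100 percent and -200:4:200 Hz
  expect_length(grid$pdff_axis, 101)
  expect_length(grid$f0_axis, 101)

  # pure-water voxel equals the scalar simulator output
  te <- echo_times(scheme_preset("bipolar3T"))
  v <- tissue_voxel(1, 0, grid$phi0_true, grid$f0_axis[1], grid$r2star_true)
  expect_equal(vol$data[1, 1, 1, ], simulate_signal(v, default_fat_spectrum(),
                                                    te),
               tolerance = 1e-12)
  # mixed voxel too
  i <- 41; j <- 73
  v <- tissue_voxel(1 - grid$pdff_axis[i] / 100, grid$pdff_axis[i] / 100,
                    grid$phi0_true, grid$f0_axis[j], grid$r2star_true)
  expect_equal(vol$data[i, j, 2, ], simulate_signal(v, default_fat_spectrum(),
                                                    te),
               tolerance = 1e-12)

  # repetitions identical before noise
  expect_identical(vol$data[, , 1, ], vol$data[, , 2, ])
})

test_that("normalization is 99% of the first-echo maximum and idempotent", {
  grid <- silico_grid(pdff_axis = c(0, 50, 100), f0_axis = c(0, 100),
                      n_reps = 1)
  vol <- generate_silico_volume(grid, scheme_preset("bipolar3T"))
  vol$data <- vol$data * (2 / max(Mod(vol$data[, , , 1, drop = FALSE])))
  nv <- normalize_volume(vol)
  expect_equal(nv$meta$norm_scale, 1 / 1.98, tolerance = 1e-12)
  expect_equal(max(Mod(nv$data[, , , 1])), 1 / 0.99, tolerance = 1e-12)

  # idempotent and scale invariant
  nv2 <- normalize_volume(nv)
  expect_equal(nv2$data, nv$data, tolerance = 1e-12)
  vol5 <- vol; vol5$data <- vol5$data * 5
  expect_equal(normalize_volume(vol5)$data, nv$data, tolerance = 1e-12)

  vol$data[] <- 0i
  expect_error(normalize_volume(vol), "all-zero")
})

test_that("complex noise follows the SNR convention and is reproducible", {
  grid <- silico_grid(n_reps = 13)
  vol <- normalize_volume(generate_silico_volume(grid,
                                                 scheme_preset("monopolar3T")))
  noisy <- add_complex_noise(vol, 10, seed = 7)
  resid <- noisy$data - vol$data
  expect_gt(length(resid), 1e6)
  # sigma per component = 1/(sqrt(2) snr)
  expect_equal(sd(Re(resid)), 1 / (sqrt(2) * 10), tolerance = 0.01)
  expect_equal(sd(Im(resid)), 1 / (sqrt(2) * 10), tolerance = 0.01)
  expect_lt(abs(mean(Re(resid))), 1e-3)

  # determinism and near-identity at enormous SNR
  again <- add_complex_noise(vol, 10, seed = 7)
  expect_identical(noisy$data, again$data)
  clean <- add_complex_noise(vol, 1e12, seed = 7)
  expect_equal(clean$data, vol$data, tolerance = 1e-9)
  expect_error(add_complex_noise(vol, -5, 1), "> 0")
})

test_that("vial phantom carries the reference fractions and labels", {
  phan <- generate_vial_phantom(snr = Inf)
  expect_setequal(sort(unique(as.vector(phan$labels))), 0:8)

  # ROI ground truth: per-label PDFF of the noiseless volume equals the
  # requested fraction (fit-free check through the generating amplitudes)
  fr <- c(0, 8.5, 20, 37, 63.2, 85.4, 92.1, 100)
  te <- phan$volume$echo_times_s
  for (k in c(1, 4, 8)) {
    sig <- phan$volume$data[, , 1, ][phan$labels[, , 1] == k]
    v <- tissue_voxel(1 - fr[k] / 100, fr[k] / 100, 30, 0, 50)
    ref <- simulate_signal(v, default_fat_spectrum(), te)[1] *
      phan$volume$meta$norm_scale
    expect_equal(unique(sig[abs(sig - sig[1]) < 1e-12]), ref,
                 tolerance = 1e-9)
  }
  expect_error(generate_vial_phantom(shape = c(6, 6, 2)), "vials")
  expect_error(generate_vial_phantom(fractions = c(-5, 50)), "\\[0,100\\]")
})

test_that("roi_stats summarizes labelled maps", {
  m <- array(c(1, 1, 2, 2, 3, 3), dim = c(6, 1, 1))
  l <- array(c(1L, 1L, 2L, 2L, 0L, 0L), dim = c(6, 1, 1))
  st <- roi_stats(m, l)
  expect_equal(st$mean, c(1, 2))
  expect_equal(st$n, c(2, 2))
})
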