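# disk-limited Cartesian DFT of the analytic phantom: the band-limited
# reference a radial reconstruction can aim for
cartesian_reference <- function(ph, n, fov, t = 0) {
  xs <- (seq_len(n) - (n + 1) / 2) / n * fov
  kxs <- (seq_len(n) - (n / 2 + 1)) / fov
  kg <- as.matrix(expand.grid(kx = kxs, ky = kxs))
  keep <- sqrt(rowSums(kg^2)) <= n / (2 * fov)
  E <- exp(2i * pi * (outer(rep(xs, n), kg[keep, 1]) +
                        outer(rep(xs, each = n), kg[keep, 2])))
  matrix(E %*% phantom_kspace(ph, kg[keep, , drop = FALSE], t), n, n) / fov^2
}

radial_samples <- function(ph, n_spokes, n, fov, nsa = 2L * n, noise_sd = 0,
                           seed = 4, uniform = FALSE) {
  kmax <- n / (2 * fov)
  kr <- seq(-kmax, kmax, length.out = nsa + 1L)[-(nsa + 1L)]
  angles <- if (uniform) (seq_len(n_spokes) - 1) * pi / n_spokes else
    (seq_len(n_spokes) - 1) * pi * (3 - sqrt(5))
  set.seed(seed)
  y <- c(); k <- NULL
  for (a in angles) {
    kk <- cbind(kr * cos(a), kr * sin(a))
    k <- rbind(k, kk)
    yy <- phantom_kspace(ph, kk, 0)
    if (noise_sd > 0) {
      yy <- yy + complex(real = rnorm(nsa, sd = noise_sd),
                         imaginary = rnorm(nsa, sd = noise_sd))
    }
    y <- c(y, yy)
  }
  list(y = y, k = k)
}

test_that("SVD coil compression thresholds and reconstructs", {
  # rank-1 coil set collapses to one virtual coil
  set.seed(9)
  base <- complex(real = rnorm(200), imaginary = rnorm(200))
  kd <- array(0i, dim = c(20, 10, 4))
  for (cc in 1:4) kd[, , cc] <- base * (0.5 + 0.1 * cc)
  cmp1 <- svd_coil_compress(kd, threshold = 0.02)
  expect_equal(cmp1$n_virtual, 1L)
  expect_gt(cmp1$energy_retained, 0.999999)

  # threshold 0 keeps everything and the basis is unitary: exact round trip
  kd2 <- array(complex(real = rnorm(800), imaginary = rnorm(800)),
               dim = c(20, 10, 4))
  cmp0 <- svd_coil_compress(kd2, threshold = 0)
  expect_equal(cmp0$n_virtual, 4L)
  X <- matrix(kd2, ncol = 4)
  back <- matrix(cmp0$kdata, ncol = 4) %*% Conj(t(cmp0$basis))
  expect_equal(back, X, tolerance = 1e-10)

  # smooth 24-coil phantom: compressed recon close to full-coil recon
  acq <- simulate_free_running_2d(generate_dynamic_phantom(),
                                  n_segments = 20, n_coils = 24,
                                  noise_sd = 0, seed = 2)
  cmp <- svd_coil_compress(acq$kdata)
  sel <- which(!acq$is_si)[1:80]
  kk <- NULL
  for (s in sel) kk <- rbind(kk, acq$k[, , s])
  sos <- function(kd) {
    acc <- 0
    for (cc in seq_len(dim(kd)[3])) {
      img <- nufft_gridding_recon(as.vector(kd[, sel, cc]), kk,
                                  acq$matrix_size, acq$fov_m,
                                  n_spokes = length(sel))
      acc <- acc + Mod(img)^2
    }
    sqrt(acc)
  }
  full <- sos(acq$kdata)
  compd <- sos(cmp$kdata)
  expect_lt(sqrt(sum((compd - full)^2) / sum(full^2)), 0.01)
})

test_that("gridding reconstruction meets the radial benchmark", {
  ph <- generate_dynamic_phantom(resp_amp_m = 0, card_amp_frac = 0)
  n <- 24; fov <- 0.22
  rs <- radial_samples(ph, 64, n, fov, uniform = TRUE)
  img <- nufft_gridding_recon(rs$y, rs$k, n, fov, n_spokes = 64)
  ref <- cartesian_reference(ph, n, fov)
  expect_lt(sqrt(sum(Mod(img - ref)^2) / sum(Mod(ref)^2)), 0.05)

  # all-zero data -> all-zero image; empty input warns
  z <- nufft_gridding_recon(complex(nrow(rs$k)), rs$k, n, fov, n_spokes = 64)
  expect_equal(max(Mod(z)), 0)
  expect_warning(nufft_gridding_recon(complex(0), matrix(0, 0, 2), n, fov),
                 "empty")
})

test_that("ADMM-TV improves on gridding for undersampled sparse phantoms", {
  ph <- generate_dynamic_phantom(resp_amp_m = 0, card_amp_frac = 0)
  n <- 24; fov <- 0.22
  ref <- cartesian_reference(ph, n, fov)
  nrmse <- function(img) sqrt(sum(Mod(img - ref)^2) / sum(Mod(ref)^2))
  rs <- radial_samples(ph, 5, n, fov, noise_sd = 1e-5)
  grid_img <- nufft_gridding_recon(rs$y, rs$k, n, fov, n_spokes = 5)
  cs <- admm_tv_recon(list(list(rs$y)), list(list(rs$k)), n, fov)
  expect_gte(1 - nrmse(cs$images[, , 1, 1]) / nrmse(grid_img), 0.30)

  # objective non-increasing (monitored) on this run too
  expect_true(all(diff(cs$objective) <= 1e-6 * cs$objective[-1]))
})

test_that("zero regularization reproduces the least-squares solution", {
  ph <- generate_dynamic_phantom(resp_amp_m = 0, card_amp_frac = 0)
  n <- 16; fov <- 0.22
  rs <- radial_samples(ph, 40, n, fov, uniform = TRUE)
  cfg <- recon_config(lambda_s = 0, lambda_c = 0, lambda_r = 0, n_iter = 2)
  cs <- admm_tv_recon(list(list(rs$y)), list(list(rs$k)), n, fov, cfg)
  # independent minimum-norm least squares via truncated eigendecomposition
  # (the radial disk leaves the square's k-space corners unsampled, so the
  # plain normal equations are rank-deficient)
  w <- freerunfw:::radial_dcf(rs$k, 40, 1 / fov) / (fov / n)^2
  A <- freerunfw:::ndft_matrix(rs$k, n, fov)
  WA <- sqrt(w) * A
  G <- crossprod(Conj(WA), WA)
  b <- Conj(t(WA)) %*% (sqrt(w) * rs$y)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > 1e-6 * max(eg$values)
  xmn <- eg$vectors[, keep] %*%
    ((Conj(t(eg$vectors[, keep])) %*% b) / eg$values[keep])
  expect_lt(sqrt(sum(Mod(as.vector(cs$images[, , 1, 1]) - xmn)^2) /
                   sum(Mod(xmn)^2)), 0.05)
})

test_that("motion-resolved demo runs the reference protocol settings", {
  acq <- cached_free_running()
  sg <- extract_selfgating(acq)
  bins <- assign_bins(sg, acq$t_s[!acq$is_si])
  cmp <- svd_coil_compress(acq$kdata[, !acq$is_si, , drop = FALSE])
  yb <- bin_kspace(acq, bins, cmp$kdata[, , 1])
  rec <- admm_tv_recon(yb$y, yb$k, acq$matrix_size, acq$fov_m)
  expect_true(rec$converged)
  expect_equal(dim(rec$images), c(acq$matrix_size, acq$matrix_size,
                                  bins$n_card_bins, bins$n_resp_bins))
  # objective non-increasing after iteration 2 with the default weights
  d <- diff(rec$objective)
  expect_true(all(d[-1] <= 1e-6 * rec$objective[-c(1, length(rec$objective))]))
  # spoke conservation through binning
  expect_equal(sum(vapply(unlist(yb$y, recursive = FALSE), length,
                          integer(1))),
               acq$n_samples * sum(!acq$is_si))
})

test_that("echo inconsistency falls with trajectory correction", {
  demo <- trajectory_artifact_demo()
  expect_lt(demo$metric_corrected, demo$metric_nominal)
  # identical images give zero inconsistency
  expect_equal(echo_inconsistency(demo$images_nominal[[1]],
                                  demo$images_nominal[[1]]), 0)
})
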