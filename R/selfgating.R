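#' Simulate a free-running 2D radial acquisition of the dynamic phantom
#'
#' Desk-scale analogue of the free-running acquisition: continuous
#' golden-angle 2D radial sampling with a superior-inferior (here: fixed
#' vertical) projection spoke at the start of every segment for self-gating,
#' smooth synthetic coil sensitivities, and exact analytic k-space data from
#' the moving phantom (motion frozen within each readout).
#'
#' @param phantom A [generate_dynamic_phantom()].
#' @param n_segments Number of segments (one SI spoke each).
#' @param trs_per_segment Spokes per segment including the SI spoke.
#' @param tr_s Repetition time (s).
#' @param n_samples Samples per spoke (full diameter).
#' @param matrix_size Target image matrix (sets kmax).
#' @param n_coils Number of synthetic coils (1 = uniform sensitivity).
#' @param noise_sd Complex noise sd per component (k-space units).
#' @param seed RNG seed.
#' @return List of class `free_running_data`: `kdata`
#'   (n_samples x n_spokes x n_coils), `k` (n_samples x 2 x n_spokes, 1/m),
#'   `t_s`, `angle`, `is_si`, `coil_maps`, `fs_si_hz`, geometry fields, and
#'   the generating phantom.
#' @export
simulate_free_running_2d <- function(phantom = generate_dynamic_phantom(),
                                     n_segments = 80L, trs_per_segment = 13L,
                                     tr_s = 0.015, n_samples = 48L,
                                     matrix_size = 24L, n_coils = 6L,
                                     noise_sd = 0, seed = 1L) {
  n_spokes <- n_segments * trs_per_segment
  pos <- rep(seq_len(trs_per_segment), n_segments)
  is_si <- pos == 1L
  golden <- pi * (3 - sqrt(5))
  angle <- numeric(n_spokes)
  angle[!is_si] <- (seq_len(sum(!is_si)) - 1) * golden
  angle[is_si] <- pi / 2                       # vertical projection spoke
  t_s <- (seq_len(n_spokes) - 1) * tr_s
  kmax <- matrix_size / (2 * phantom$fov_m)
  kr <- seq(-kmax, kmax, length.out = n_samples + 1L)[-(n_samples + 1L)]
  # coil sensitivities on a ring around the FOV, smooth gaussian profiles
  xs <- (seq_len(matrix_size) - (matrix_size + 1) / 2) / matrix_size *
    phantom$fov_m
  coil_maps <- array(1i * 0 + 1, dim = c(matrix_size, matrix_size, n_coils))
  if (n_coils > 1L) {
    X <- matrix(xs, matrix_size, matrix_size)
    Y <- matrix(xs, matrix_size, matrix_size, byrow = TRUE)
    ang_c <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
    for (cc in seq_len(n_coils)) {
      px <- 0.45 * phantom$fov_m * cos(ang_c[cc])
      py <- 0.45 * phantom$fov_m * sin(ang_c[cc])
      mag <- exp(-((X - px)^2 + (Y - py)^2) / (2 * (0.35 * phantom$fov_m)^2))
      coil_maps[, , cc] <- mag * exp(1i * (0.8 * cc + 2 * pi * 0.3 *
                                             (X * cos(ang_c[cc]) +
                                                Y * sin(ang_c[cc])) /
                                             phantom$fov_m))
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  kdata <- array(0i, dim = c(n_samples, n_spokes, n_coils))
  karr <- array(0, dim = c(n_samples, 2L, n_spokes))
  for (i in seq_len(n_spokes)) {
    kxy <- cbind(kr * cos(angle[i]), kr * sin(angle[i]))
    karr[, , i] <- kxy
    for (cc in seq_len(n_coils)) {
      kdata[, i, cc] <- phantom_kspace_coil(phantom, kxy, t_s[i],
                                            coil_maps[, , cc], xs)
    }
  }
  if (noise_sd > 0) {
    n <- length(kdata)
    kdata <- kdata + complex(real = rnorm(n, sd = noise_sd),
                             imaginary = rnorm(n, sd = noise_sd))
  }
  structure(
    list(kdata = kdata, k = karr, t_s = t_s, angle = angle, is_si = is_si,
         coil_maps = coil_maps, fs_si_hz = 1 / (tr_s * trs_per_segment),
         fov_m = phantom$fov_m, matrix_size = matrix_size,
         n_samples = n_samples, phantom = phantom, tr_s = tr_s,
         noise_sd = noise_sd, seed = seed),
    class = "free_running_data"
  )
}

# analytic coil-weighted phantom k-space: FT(phantom * coil map) evaluated
# by convolving the phantom's exact transform with the (small) image-domain
# coil map via direct summation on the coil grid. For uniform maps this is
# the exact phantom transform.
phantom_kspace_coil <- function(ph, k, t, coil_map, xs) {
  if (all(Mod(coil_map - coil_map[1]) < 1e-12)) {
    return(coil_map[1] * phantom_kspace(ph, k, t))
  }
  n <- length(xs)
  img <- phantom_image(ph, n, t) * coil_map
  # direct non-uniform DFT of the n x n coil-weighted image
  px <- rep(xs, times = n)
  py <- rep(xs, each = n)
  E <- exp(-2i * pi * (outer(k[, 1], px) + outer(k[, 2], py)))
  dA <- (xs[2] - xs[1])^2
  as.complex(E %*% as.vector(img)) * dA
}

#' Extract respiratory and cardiac self-gating signals
#'
#' Principal-component analysis of the SI projection-profile stack followed
#' by band-pass filtering: the profile time series is decomposed by SVD, the
#' component with the largest in-band energy fraction is selected per band
#' (respiratory 0.05-0.5 Hz, cardiac 0.5-3 Hz, clipped below Nyquist), and
#' zero-phase Butterworth filtering yields the two gating signals at the
#' segment rate (~5 Hz for the reference protocol).
#'
#' @param data A `free_running_data` (or a complex profile matrix
#'   n_points x n_si with attribute `fs_hz`).
#' @param resp_band_hz,cardiac_band_hz Band edges (Hz).
#' @param n_pc Number of principal components examined.
#' @return An object of class `selfgating_series`: `t_s`, `resp`, `card`
#'   (unit variance), `fs_hz`, and the selected component indices.
#' @export
extract_selfgating <- function(data, resp_band_hz = c(0.05, 0.5),
                               cardiac_band_hz = c(0.5, 3), n_pc = 5L) {
  if (inherits(data, "free_running_data")) {
    si_idx <- which(data$is_si)
    if (length(si_idx) < 10L) stop("need at least 10 SI projections")
    fs <- data$fs_si_hz
    t_si <- data$t_s[si_idx]
    # projection profiles: 1D inverse FFT of each SI spoke, all coils
    prof <- NULL
    for (cc in seq_len(dim(data$kdata)[3L])) {
      lines <- data$kdata[, si_idx, cc]
      p <- Mod(apply(lines, 2L, function(v) fft(v, inverse = TRUE)))
      prof <- rbind(prof, p)
    }
  } else {
    prof <- Mod(data)
    fs <- attr(data, "fs_hz")
    if (is.null(fs)) stop("profile matrix must carry attribute `fs_hz`")
    if (ncol(prof) < 10L) stop("need at least 10 SI projections")
    t_si <- (seq_len(ncol(prof)) - 1) / fs
  }
  X <- t(prof)                                  # n_si x features
  X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X, nu = min(n_pc, ncol(X)), nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))

  nyq <- fs / 2
  # fine-grid periodogram peak: frequency and power of the dominant line
  fine_peak <- function(s, flo, fhi) {
    fg <- seq(flo, fhi, by = 0.002)
    P <- Mod(exp(-2i * pi * outer(fg, t_si)) %*% s)^2
    i <- which.max(P)
    c(freq = fg[i], power = P[i])
  }
  bandpass <- function(s, band) {
    lo <- band[1] / nyq
    hi <- min(band[2], 0.98 * nyq) / nyq
    if (lo >= hi) stop("band does not fit below Nyquist")
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    signal::filtfilt(bf, s)
  }

  # respiratory component: dominant line in the respiratory band
  rp <- apply(scores, 2L, fine_peak, flo = resp_band_hz[1],
              fhi = min(resp_band_hz[2], 0.98 * nyq))
  j_resp <- which.max(rp["power", ])
  f_resp <- rp["freq", j_resp]
  resp_sig <- bandpass(scores[, j_resp], resp_band_hz)

  # cardiac component: respiratory-driven content -- including all harmonics
  # and leakage of the sharp-edged profile displacement, which reach well
  # into the cardiac band -- is a static function of the respiratory state,
  # so it is removed by regressing every score onto a spline basis of the
  # respiratory signal; the cardiac rhythm (a different frequency) survives
  resid <- if (sd(resp_sig) > 1e-12 * max(abs(scores), 1e-30)) {
    S <- cbind(1, splines::ns(resp_sig, df = 8L))
    scores - S %*% qr.solve(S, scores)
  } else scores                         # degenerate (e.g. static) input

  cp <- apply(resid, 2L, fine_peak, flo = cardiac_band_hz[1],
              fhi = min(cardiac_band_hz[2], 0.98 * nyq))
  j_card <- which.max(cp["power", ])
  card_sig <- bandpass(resid[, j_card], cardiac_band_hz)

  resp <- list(signal = resp_sig / max(sd(resp_sig), 1e-30), pc = j_resp,
               peak_hz = f_resp, power = stats::var(resp_sig))
  card <- list(signal = card_sig / max(sd(card_sig), 1e-30), pc = j_card,
               peak_hz = cp["freq", j_card], power = stats::var(card_sig))
  structure(
    list(t_s = t_si, resp = resp$signal, card = card$signal, fs_hz = fs,
         pc_resp = resp$pc, pc_card = card$pc,
         resp_peak_hz = resp$peak_hz, card_peak_hz = card$peak_hz,
         resp_power = resp$power, card_power = card$power),
    class = "selfgating_series"
  )
}

#' Assign spokes to respiratory and cardiac bins
#'
#' Respiratory bins are equal-count amplitude quantiles of the interpolated
#' respiratory signal; cardiac bins are fixed-width windows counted from
#' each detected cardiac trigger (peak of the band-passed cardiac signal),
#' with spokes beyond the last full window of a beat collected in the final
#' bin. The number of cardiac bins follows the median beat length
#' (`floor(RR / width)`), as in subject-specific binning.
#'
#' @param series A `selfgating_series`.
#' @param spoke_times_s Times of the spokes to bin (s).
#' @param n_resp_bins Number of respiratory bins.
#' @param cardiac_bin_ms Cardiac bin width (ms).
#' @return An object of class `binning_plan`: `resp_bin`, `card_bin`
#'   (integers per spoke), `n_resp_bins`, `n_card_bins`, `triggers_s`,
#'   `rr_s`.
#' @export
assign_bins <- function(series, spoke_times_s, n_resp_bins = 4L,
                        cardiac_bin_ms = 100) {
  stopifnot(inherits(series, "selfgating_series"))
  resp_i <- approx(series$t_s, series$resp, xout = spoke_times_s,
                   rule = 2)$y
  qs <- quantile(resp_i, probs = seq(0, 1, length.out = n_resp_bins + 1L))
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  resp_bin <- as.integer(cut(resp_i, qs, labels = FALSE, include.lowest = TRUE))

  # cardiac triggers: peaks of the (upsampled) cardiac signal
  t_fine <- seq(min(series$t_s), max(series$t_s), by = 1 / (series$fs_hz * 10))
  card_fine <- stats::spline(series$t_s, series$card, xout = t_fine)$y
  pk <- pracma::findpeaks(card_fine,
                          minpeakheight = 0.3 * max(card_fine),
                          minpeakdistance = round(0.3 * series$fs_hz * 10))
  if (is.null(pk) || nrow(pk) < 2L) stop("no cardiac triggers detected")
  trig <- sort(t_fine[pk[, 2L]])
  rr <- median(diff(trig))
  width <- cardiac_bin_ms * 1e-3
  n_card_bins <- max(1L, floor(rr / width))
  # extrapolate one trigger before the first for early spokes
  trig_ext <- c(trig[1L] - rr * ceiling((trig[1L] - min(spoke_times_s)) / rr + 1),
                trig)
  last_trig <- trig_ext[findInterval(spoke_times_s, trig_ext)]
  phase <- spoke_times_s - last_trig
  card_bin <- pmin(floor(phase / width) + 1L, n_card_bins)
  structure(
    list(resp_bin = resp_bin, card_bin = as.integer(card_bin),
         n_resp_bins = as.integer(n_resp_bins),
         n_card_bins = as.integer(n_card_bins),
         triggers_s = trig, rr_s = rr, cardiac_bin_ms = cardiac_bin_ms),
    class = "binning_plan"
  )
}
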