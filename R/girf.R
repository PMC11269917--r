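#' Gradient waveform container
#'
#' Gradient amplitude samples on a uniform raster, one column per physical
#' axis.
#'
#' @param G Numeric matrix (n x n_axes) of gradient amplitudes (mT/m), or a
#'   vector for a single axis.
#' @param dt Raster time (s).
#' @param axes Axis labels.
#' @return An object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(G, dt = 10e-6, axes = NULL) {
  if (is.vector(G)) G <- matrix(G, ncol = 1L)
  if (!all(is.finite(G))) stop("gradient samples must be finite")
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  if (is.null(axes)) axes <- c("x", "y", "z")[seq_len(ncol(G))]
  colnames(G) <- axes
  structure(list(G = G, dt = dt, axes = axes), class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform> %d samples x %d axes, raster %.1f us, max |G| %.2f mT/m\n",
              nrow(x$G), ncol(x$G), x$dt * 1e6, max(abs(x$G))))
  invisible(x)
}

# symmetric FFT frequency grid for n samples at raster dt
fft_freqs <- function(n, dt) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / (n * dt)
}

#' Synthesize a gradient-system frequency response
#'
#' Builds a per-axis linear time-invariant gradient-chain model
#' `H(f) = exp(-i 2 pi f tau) * lowpass(f) * prod notch(f)`: a pure group
#' delay, a smooth high-frequency loss (Butterworth-type magnitude), and
#' mechanical-resonance notches. Defaults mimic a clinical gradient chain
#' qualitatively: notches between 3.3 and 4 kHz, a ~2.5 us delay on the z
#' axis, and a decreasing transfer function at high frequencies.
#'
#' @param delay_per_axis_s Group delay per axis (s).
#' @param resonance_freqs_hz Notch center frequencies (Hz), shared by axes.
#' @param resonance_depth Fractional notch depth(s) in (0, 1).
#' @param resonance_width_hz Notch half-width(s) (Hz).
#' @param lowpass_cutoff_hz -3 dB cutoff of the loss term (Hz); `Inf`
#'   disables it.
#' @param lowpass_order Butterworth magnitude order.
#' @param f_max_hz Frequency support; response is 0 beyond it (tapered).
#' @param df_hz Frequency grid step (Hz).
#' @return An object of class `girf_model` with the frequency grid, complex
#'   response per axis and per-axis equivalent delay estimates.
#' @export
synth_gradient_system <- function(delay_per_axis_s = c(x = 1.0e-6, y = 1.5e-6,
                                                       z = 2.5e-6),
                                  resonance_freqs_hz = c(3400, 3900),
                                  resonance_depth = 0.15,
                                  resonance_width_hz = 150,
                                  lowpass_cutoff_hz = 9000,
                                  lowpass_order = 2,
                                  f_max_hz = 50e3, df_hz = 50) {
  if (!is.infinite(lowpass_cutoff_hz) && lowpass_cutoff_hz <= 0) {
    stop("`lowpass_cutoff_hz` must be > 0")
  }
  n_axes <- length(delay_per_axis_s)
  axes <- names(delay_per_axis_s)
  if (is.null(axes)) axes <- c("x", "y", "z")[seq_len(n_axes)]
  f <- seq(-f_max_hz, f_max_hz, by = df_hz)
  depth <- rep_len(resonance_depth, length(resonance_freqs_hz))
  width <- rep_len(resonance_width_hz, length(resonance_freqs_hz))
  mag <- rep(1, length(f))
  if (is.finite(lowpass_cutoff_hz)) {
    mag <- mag / sqrt(1 + (f / lowpass_cutoff_hz)^(2 * lowpass_order))
  }
  for (i in seq_along(resonance_freqs_hz)) {
    # Lorentzian notch applied symmetrically in |f| (Hermitian-safe)
    mag <- mag * (1 - depth[i] / (1 + ((abs(f) - resonance_freqs_hz[i]) /
                                         width[i])^2))
  }
  H <- sapply(delay_per_axis_s, function(tau) mag * exp(-2i * pi * f * tau))
  colnames(H) <- axes
  structure(
    list(freq_hz = f, H = H, axes = axes,
         delay_s = setNames(as.numeric(delay_per_axis_s), axes),
         params = list(resonance_freqs_hz = resonance_freqs_hz,
                       lowpass_cutoff_hz = lowpass_cutoff_hz)),
    class = "girf_model"
  )
}

#' @export
print.girf_model <- function(x, ...) {
  cat(sprintf("<girf_model> axes %s, grid +/-%.0f kHz (%d points)\n",
              paste(x$axes, collapse = "/"), max(x$freq_hz) / 1e3,
              length(x$freq_hz)))
  cat(sprintf("  delays: %s us\n",
              paste(sprintf("%s=%.2f", x$axes, girf_delay(x) * 1e6),
                    collapse = ", ")))
  invisible(x)
}

#' Equivalent group delay of a GIRF
#'
#' Weighted least-squares slope of the unwrapped response phase over the
#' well-conditioned band (|H| > half its low-frequency value), per axis:
#' a pure delay has phase `-2 pi f tau`.
#'
#' @param girf A `girf_model`.
#' @return Named vector of delays (s).
#' @export
girf_delay <- function(girf) {
  stopifnot(inherits(girf, "girf_model"))
  out <- vapply(seq_along(girf$axes), function(a) {
    h <- girf$H[, a]
    f <- girf$freq_hz
    ord <- order(f)
    f <- f[ord]; h <- h[ord]
    i0 <- which.min(abs(f))
    h0 <- Mod(h[i0])
    # contiguous well-conditioned band around DC; spikes from weakly probed
    # frequencies (deconvolution artifacts) are excluded by the upper bound
    good <- Mod(h) > 0.5 * h0 & Mod(h) < 2 * h0
    hi <- i0; while (hi < length(f) && good[hi + 1L]) hi <- hi + 1L
    lo <- i0; while (lo > 1L && good[lo - 1L]) lo <- lo - 1L
    keep <- seq(lo, hi)
    ph <- unwrap_phase(Arg(h[keep]))
    fk <- f[keep]
    -sum(fk * ph) / (2 * pi * sum(fk^2))
  }, numeric(1))
  setNames(out, girf$axes)
}

# interpolate a girf axis response onto arbitrary frequencies (complex,
# linear on Re/Im, zero outside the stored support)
girf_interp <- function(girf, axis, f) {
  idx <- match(axis, girf$axes)
  if (is.na(idx)) stop(sprintf("axis '%s' not in GIRF", axis))
  ord <- order(girf$freq_hz)
  fg <- girf$freq_hz[ord]
  h <- girf$H[ord, idx]
  re <- approx(fg, Re(h), xout = f, rule = 2)$y
  im <- approx(fg, Im(h), xout = f, rule = 2)$y
  out <- complex(real = re, imaginary = im)
  out[f < min(fg) | f > max(fg)] <- 0i
  out
}

#' Predict the actual gradient waveform through a GIRF
#'
#' Per-axis frequency-domain multiplication of the nominal waveform with the
#' system response, using zero-padding to at least twice the waveform length
#' to avoid circular wrap-around.
#'
#' @param nominal A [gradient_waveform()].
#' @param girf A `girf_model`; axes are matched by label (a single-axis GIRF
#'   is recycled).
#' @return A [gradient_waveform()] of the same length.
#' @export
apply_girf <- function(nominal, girf) {
  stopifnot(inherits(nominal, "gradient_waveform"), inherits(girf, "girf_model"))
  n <- nrow(nominal$G)
  npad <- 2^ceiling(log2(2 * n))
  f <- fft_freqs(npad, nominal$dt)
  out <- nominal$G
  for (a in seq_len(ncol(nominal$G))) {
    ax <- nominal$axes[a]
    hax <- if (ax %in% girf$axes) ax else girf$axes[1L]
    H <- girf_interp(girf, hax, f)
    g <- c(nominal$G[, a], rep(0, npad - n))
    G_f <- fft(g)
    out[, a] <- Re(fft(G_f * H, inverse = TRUE) / npad)[seq_len(n)]
  }
  gradient_waveform(out, nominal$dt, nominal$axes)
}

#' Simulate the two off-centered slices GIRF measurement
#'
#' Simulates the thin-slice method on one axis: two slices at symmetric
#' offsets accumulate phase under the system's actual gradient; the phase
#' difference, differentiated in time, recovers the played gradient:
#' `G(t) = d/dt [phi+ - phi-] / (2 pi gamma * 2 x0)`.
#'
#' @param system A `girf_model` (the ground-truth gradient chain).
#' @param probe A single-axis [gradient_waveform()] (the nominal probe).
#' @param slice_offset_m Slice offset `x0` (m); slices sit at `+/- x0`.
#' @param noise_sd Complex noise standard deviation per component added to
#'   the unit-magnitude slice signals.
#' @param seed Noise seed.
#' @param axis GIRF axis to probe.
#' @param sys A [system_config()] for the gyromagnetic ratio.
#' @return A [gradient_waveform()] with the measured gradient (mT/m).
#' @export
thin_slice_measurement <- function(system, probe, slice_offset_m = 0.02,
                                   noise_sd = 0, seed = 1L, axis = "x",
                                   sys = system_config()) {
  stopifnot(inherits(system, "girf_model"), inherits(probe, "gradient_waveform"))
  if (slice_offset_m == 0) stop("slice separation must be nonzero")
  actual <- apply_girf(gradient_waveform(probe$G[, 1L], probe$dt, axis), system)
  gam <- sys$gamma_hz_per_t
  # phase of each slice: 2 pi gamma x0 int G dt  (G in T/m)
  phase_half <- 2 * pi * gam * slice_offset_m *
    pracma::cumtrapz(seq_len(nrow(actual$G)) * actual$dt,
                     actual$G[, 1L] * 1e-3)[, 1L]
  s_plus <- exp(1i * phase_half)
  s_minus <- exp(-1i * phase_half)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    n <- length(s_plus)
    s_plus <- s_plus + complex(real = rnorm(n, sd = noise_sd),
                               imaginary = rnorm(n, sd = noise_sd))
    s_minus <- s_minus + complex(real = rnorm(n, sd = noise_sd),
                                 imaginary = rnorm(n, sd = noise_sd))
  }
  dphi <- unwrap_phase(Arg(s_plus)) - unwrap_phase(Arg(s_minus))
  # exact inverse of the trapezoidal phase accumulation: the step sequence
  # diff(phi) is G filtered by dt (1 + z^-1)/2, deconvolved in the Fourier
  # domain (the Nyquist bin, where the filter vanishes, is zeroed)
  n <- length(dphi)
  steps <- c(0, diff(dphi))
  w <- 2 * pi * (seq_len(n) - 1) / n
  Hs <- actual$dt * (1 + exp(-1i * w)) / 2
  Gf <- fft(steps) / Hs
  Gf[Mod(Hs) < 1e-3 * actual$dt] <- 0i
  g <- Re(fft(Gf, inverse = TRUE)) / n / (2 * pi * gam * 2 * slice_offset_m)
  gradient_waveform(g * 1e3, probe$dt, axis)
}

#' Estimate a GIRF from probe/measurement pairs
#'
#' Frequency-domain input-output deconvolution with Tikhonov regularization:
#' `H(f) = sum_p conj(P_p) M_p / (sum_p |P_p|^2 + reg)`, accumulated over a
#' spectrally diverse probe set (e.g. triangular blips of varied slope).
#' Bands where the accumulated probe power falls below `band_rel_power`
#' times its maximum are masked to zero and flagged.
#'
#' @param probes List of single-axis [gradient_waveform()] probes (or one).
#' @param measured List of matching measured outputs.
#' @param reg Tikhonov weight (relative to peak probe power).
#' @param axis Axis label for the estimated response.
#' @param band_rel_power Relative power threshold for band masking.
#' @return A `girf_model` with one axis; attribute `masked_band` reports the
#'   masked frequency fraction.
#' @export
estimate_girf <- function(probes, measured, reg = 1e-6, axis = "x",
                          band_rel_power = 1e-6) {
  if (inherits(probes, "gradient_waveform")) probes <- list(probes)
  if (inherits(measured, "gradient_waveform")) measured <- list(measured)
  if (length(probes) != length(measured) || length(probes) == 0L) {
    stop("need matching, nonempty probe and measurement lists")
  }
  dt <- probes[[1L]]$dt
  npad <- 2^ceiling(log2(2 * max(vapply(probes, function(p) nrow(p$G),
                                        integer(1)))))
  num <- complex(npad)
  den <- numeric(npad)
  for (i in seq_along(probes)) {
    p <- c(probes[[i]]$G[, 1L], rep(0, npad - nrow(probes[[i]]$G)))
    m <- c(measured[[i]]$G[, 1L], rep(0, npad - nrow(measured[[i]]$G)))
    P <- fft(p); M <- fft(m)
    num <- num + Conj(P) * M
    den <- den + Mod(P)^2
  }
  H <- num / (den + reg * max(den))
  mask <- den < band_rel_power * max(den)
  H[mask] <- 0i
  f <- fft_freqs(npad, dt)
  ord <- order(f)
  model <- structure(
    list(freq_hz = f[ord], H = matrix(H[ord], ncol = 1L,
                                      dimnames = list(NULL, axis)),
         axes = axis, delay_s = NA_real_, params = list(reg = reg)),
    class = "girf_model"
  )
  model$delay_s <- girf_delay(model)
  attr(model, "masked_band") <- mean(mask)
  model
}

#' Combine single-axis GIRF models into a multi-axis model
#'
#' Interpolates each axis response onto the first model's frequency grid.
#'
#' @param models List of `girf_model` objects (one axis each).
#' @return A `girf_model` with all axes.
#' @export
combine_girf <- function(models) {
  stopifnot(length(models) >= 1L)
  f <- models[[1L]]$freq_hz
  H <- vapply(models, function(m) girf_interp(m, m$axes[1L], f),
              complex(length(f)))
  axes <- vapply(models, function(m) m$axes[1L], character(1))
  colnames(H) <- axes
  model <- structure(
    list(freq_hz = f, H = H, axes = axes, delay_s = NA_real_, params = list()),
    class = "girf_model"
  )
  model$delay_s <- girf_delay(model)
  model
}

#' Triangular probe set for GIRF estimation
#'
#' Triangular blips of graded slopes/durations, the classic spectrally
#' diverse probe family for thin-slice gradient measurements.
#'
#' @param n_probes Number of triangles.
#' @param amp_mt_m Peak amplitude (mT/m).
#' @param base_duration_s Duration of the longest triangle (s).
#' @param dt Raster (s).
#' @param pad_s Zero padding before/after each blip (s).
#' @return List of single-axis [gradient_waveform()]s.
#' @export
girf_probe_set <- function(n_probes = 8L, amp_mt_m = 30, base_duration_s = 800e-6,
                           dt = 10e-6, pad_s = 200e-6) {
  stopifnot(n_probes >= 1L)
  npad <- round(pad_s / dt)
  lapply(seq_len(n_probes), function(i) {
    dur <- base_duration_s * (1 - 0.08 * (i - 1))
    nup <- max(2L, round(dur / (2 * dt)))
    tri <- c(seq(0, 1, length.out = nup), seq(1, 0, length.out = nup)[-1L])
    g <- c(rep(0, npad), amp_mt_m * tri, rep(0, npad))
    gradient_waveform(g, dt)
  })
}

#' Integrate a gradient waveform to a k-space trajectory
#'
#' `k(t) = gamma * int_0^t G dt'`, trapezoidal rule, expressed in grid-point
#' units (`1/FOV` increments). Optional echo segmentation attaches per-echo
#' sample indices.
#'
#' @param grad A [gradient_waveform()] (mT/m).
#' @param system A [system_config()].
#' @param fov_m Field of view (m).
#' @param echo_samples Optional list of sample-index vectors, one per echo.
#' @param echo_parity Optional parity labels ("odd"/"even") per echo.
#' @return An object of class `k_trajectory`: `k` (n x n_axes, grid points),
#'   `t_s`, and optional echo segmentation.
#' @export
integrate_trajectory <- function(grad, system = system_config(), fov_m = 0.22,
                                 echo_samples = NULL, echo_parity = NULL) {
  stopifnot(inherits(grad, "gradient_waveform"))
  t <- (seq_len(nrow(grad$G)) - 1) * grad$dt
  k <- apply(grad$G, 2L, function(g) {
    system$gamma_hz_per_t * pracma::cumtrapz(t, g * 1e-3)[, 1L] * fov_m
  })
  structure(
    list(k = k, t_s = t, dt = grad$dt, fov_m = fov_m, axes = grad$axes,
         echo_samples = echo_samples, echo_parity = echo_parity),
    class = "k_trajectory"
  )
}

#' Mean k-space sample shift by echo parity
#'
#' Mean along-readout displacement of the actual vs nominal k-space sample
#' positions (grid-point units), aggregated over even- and odd-numbered
#' echoes separately. Readout direction is taken from the nominal
#' trajectory; displacement is signed along it.
#'
#' @param nominal,actual `k_trajectory` objects with matching echo
#'   segmentation.
#' @return Named vector `c(even = ..., odd = ...)` in grid points.
#' @export
echo_parity_shift <- function(nominal, actual) {
  stopifnot(inherits(nominal, "k_trajectory"), inherits(actual, "k_trajectory"))
  if (!all(dim(nominal$k) == dim(actual$k))) {
    stop("nominal and actual trajectories are not congruent")
  }
  if (is.null(nominal$echo_samples)) stop("trajectories carry no echo segmentation")
  parities <- nominal$echo_parity
  if (is.null(parities)) {
    parities <- ifelse(seq_along(nominal$echo_samples) %% 2 == 1, "odd", "even")
  }
  # fixed spoke frame: displacement is signed along the first echo's
  # traversal direction for all echoes, so a pure gradient delay produces
  # opposite-sign shifts on odd and even echoes of a bipolar train
  idx1 <- nominal$echo_samples[[1L]]
  dir <- nominal$k[idx1[length(idx1)], ] - nominal$k[idx1[1L], ]
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-12) dir <- c(1, rep(0, ncol(nominal$k) - 1L)) else dir <- dir / nd
  shifts <- vapply(seq_along(nominal$echo_samples), function(e) {
    idx <- nominal$echo_samples[[e]]
    mean((actual$k[idx, , drop = FALSE] - nominal$k[idx, , drop = FALSE]) %*% dir)
  }, numeric(1))
  c(even = mean(shifts[parities == "even"]),
    odd = mean(shifts[parities == "odd"]))
}
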