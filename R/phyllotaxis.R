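#' Segmented 3D radial spiral-phyllotaxis plan
#'
#' Generates the spoke directions of a segmented spiral-phyllotaxis 3D
#' radial acquisition: interleaved golden-angle azimuth increments with
#' polar angles densified toward the pole (`theta_n = (pi/2) sqrt(n/N)`,
#' hemisphere coverage), reordered so that each segment sweeps smoothly from
#' pole to equator, with a superior-inferior (SI, unit z) spoke prepended to
#' every segment for self-gating. The default geometry (3078 segments of 13
#' TRs) yields 40,014 spokes per echo of which 3078 are SI projections.
#'
#' @param n_segments Number of segments.
#' @param trs_per_segment TRs (spokes) per segment, including the SI spoke.
#' @param alternate_polarity If `TRUE`, flip direction sign on alternate
#'   spokes within a segment (full-sphere coverage variant).
#' @return An object of class `phyllotaxis_plan` with fields `dir` (n x 3
#'   unit vectors), `segment`, `pos_in_segment`, `is_si`.
#' @examples
#' plan <- phyllotaxis_directions(n_segments = 10, trs_per_segment = 13)
#' sum(plan$is_si)  # 10
#' @export
phyllotaxis_directions <- function(n_segments = 3078L, trs_per_segment = 13L,
                                   alternate_polarity = FALSE) {
  n_segments <- as.integer(n_segments)
  trs_per_segment <- as.integer(trs_per_segment)
  if (n_segments < 1L || trs_per_segment < 1L) {
    stop("`n_segments` and `trs_per_segment` must be >= 1")
  }
  n_total <- n_segments * trs_per_segment
  n_phyllo <- n_segments * (trs_per_segment - 1L)
  golden <- pi * (3 - sqrt(5))            # 137.508 deg in radians

  dir <- matrix(0, n_total, 3L)
  segment <- rep(seq_len(n_segments), each = trs_per_segment)
  pos <- rep(seq_len(trs_per_segment), times = n_segments)
  is_si <- pos == 1L

  if (n_phyllo > 0L) {
    n <- seq_len(n_phyllo)
    theta <- (pi / 2) * sqrt(n / n_phyllo)   # polar angle, pole -> equator
    phi <- n * golden
    pts <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    # interleaved segment assignment: spoke j of segment s takes phyllotaxis
    # index (j-2)*n_segments + s, so every segment traverses pole-to-equator
    j <- pos[!is_si] - 1L                    # 1 .. trs_per_segment-1
    s <- segment[!is_si]
    idx <- (j - 1L) * n_segments + s
    d <- pts[idx, , drop = FALSE]
    if (alternate_polarity) {
      flip <- (pos[!is_si] %% 2L) == 0L
      d[flip, ] <- -d[flip, ]
    }
    dir[!is_si, ] <- d
  }
  dir[is_si, 3L] <- 1                        # SI spoke along +z
  structure(
    list(dir = dir, segment = segment, pos_in_segment = pos, is_si = is_si,
         n_segments = n_segments, trs_per_segment = trs_per_segment),
    class = "phyllotaxis_plan"
  )
}

#' @export
print.phyllotaxis_plan <- function(x, ...) {
  cat(sprintf("<phyllotaxis_plan> %d spokes (%d segments x %d TRs), %d SI projections\n",
              nrow(x$dir), x$n_segments, x$trs_per_segment, sum(x$is_si)))
  invisible(x)
}

#' Multi-echo radial readout design
#'
#' Hardware and sampling parameters for the readout gradient of one spoke.
#'
#' @param fov_mm Field of view (mm).
#' @param matrix_size Readout matrix (samples across the FOV diameter).
#' @param bw_per_pixel_hz Receiver bandwidth per pixel (Hz/px).
#' @param g_max_mt_m Gradient amplitude limit (mT/m).
#' @param slew_max_t_m_s Slew-rate limit (T/m/s).
#' @param raster_s Gradient raster time (s).
#' @return An object of class `readout_design`.
#' @export
readout_design <- function(fov_mm = 220, matrix_size = 147L,
                           bw_per_pixel_hz = 1510, g_max_mt_m = 60,
                           slew_max_t_m_s = 200, raster_s = 10e-6) {
  structure(
    list(fov_mm = fov_mm, matrix_size = as.integer(matrix_size),
         bw_per_pixel_hz = bw_per_pixel_hz, g_max_mt_m = g_max_mt_m,
         slew_max_t_m_s = slew_max_t_m_s, raster_s = raster_s),
    class = "readout_design"
  )
}

#' Build the multi-echo readout gradient of one spoke
#'
#' Constructs the unit-direction readout waveform for a monopolar or bipolar
#' echo train: trapezoidal lobes traversing the full k-space diameter
#' (-kmax to +kmax) each echo, with alternating polarity (bipolar) or
#' same-polarity lobes separated by flyback rewinders (monopolar), preceded
#' by a prephaser that places the first k-space-center crossing at TE1.
#' Echo centers land on the scheme's echo times within one raster step; the
#' flat-top duration is rounded to the raster and the effective bandwidth
#' recorded. Infeasible timing (echo spacing shorter than the minimum lobe,
#' or amplitude/slew limits exceeded) raises an error naming the constraint.
#'
#' @param design A [readout_design()].
#' @param scheme An [echo_scheme()].
#' @param system A [system_config()].
#' @return A single-axis [gradient_waveform()] with attributes:
#'   `echo_center_idx`, `echo_samples` (ADC sample indices per echo),
#'   `sample_times_s`, `echo_parity`, `kmax_grid` and the achieved timing.
#' @export
build_readout <- function(design = readout_design(), scheme,
                          system = system_config()) {
  stopifnot(inherits(design, "readout_design"), inherits(scheme, "echo_scheme"))
  dt <- design$raster_s
  gam <- system$gamma_hz_per_t
  fov <- design$fov_mm * 1e-3
  nx <- design$matrix_size
  # flat-top: nx samples at dwell 1/(bw*nx); rounded to raster
  t_flat <- round(1 / design$bw_per_pixel_hz / dt) * dt
  dwell <- t_flat / nx
  # plateau amplitude to traverse 2*kmax = nx/fov during the flat top
  g_amp <- nx / fov / (gam * t_flat) * 1e3            # mT/m
  if (g_amp > design$g_max_mt_m) {
    stop(sprintf("readout amplitude %.1f mT/m exceeds limit %.1f mT/m",
                 g_amp, design$g_max_mt_m))
  }
  n_ramp <- ceiling(g_amp * 1e-3 / design$slew_max_t_m_s / dt)
  t_ramp <- n_ramp * dt
  n_flat <- round(t_flat / dt)
  te <- echo_times(scheme)
  dte <- round(scheme$dte_ms * 1e-3 / dt) * dt
  if (n_flat %% 2L == 1L) n_flat <- n_flat + 1L      # even: center on a sample
  # lobe: ramp to amp, stay at amp for n_flat+1 samples (t_flat between the
  # first and last at-amplitude sample), ramp down; symmetric about its
  # center sample
  ramp_up <- seq_len(n_ramp) / n_ramp
  lobe <- c(ramp_up, rep(1, n_flat - 1L), rev(ramp_up))
  n_lobe <- length(lobe)
  j_center <- n_ramp + n_flat / 2                     # lobe-local center sample
  n_gap <- round(dte / dt) - n_lobe
  if (n_gap < 0L) {
    stop(sprintf(
      "echo spacing %.2f ms shorter than minimum lobe duration %.2f ms (flat %.2f ms + ramps %.2f ms)",
      scheme$dte_ms, n_lobe * dt * 1e3, t_flat * 1e3, 2 * t_ramp * 1e3))
  }

  # first readout: lobe center on TE1
  te1 <- round(scheme$te1_ms * 1e-3 / dt) * dt
  i_ramp1 <- round(te1 / dt) + 1L - j_center + 1L     # first lobe sample index
  if (i_ramp1 < 2L) stop("TE1 too short: first readout ramp precedes t = 0")

  n_buf <- max(round(scheme$tr_ms * 1e-3 / dt),
               i_ramp1 + (scheme$n_echoes - 1L) * round(dte / dt) + n_lobe + 1L)
  g <- numeric(n_buf)
  echo_center_idx <- integer(scheme$n_echoes)
  echo_samples <- vector("list", scheme$n_echoes)
  sample_times <- numeric(0)

  # discrete (trapezoidal-rule) area of the first half-lobe, start to center;
  # prephaser and rewinders are rescaled against it so every echo center
  # crosses k = 0 exactly under the same integration rule
  lobe_probe <- c(0, g_amp * lobe, 0)
  cum_probe <- pracma::cumtrapz(seq_along(lobe_probe) * dt, lobe_probe)[, 1L]
  a_half <- cum_probe[1L + j_center]

  # prephaser: area -a_half, finishing just before the first ramp
  n_pre_avail <- i_ramp1 - 1L
  pre <- trapezoid_lobe(-a_half, n_pre_avail, design, dt)
  pre_area <- pracma::trapz(seq_along(pre) * dt, pre)
  if (abs(pre_area) > 0) pre <- pre * (-a_half / pre_area)
  g[seq_along(pre)] <- pre

  pol <- 1
  i_lobe <- i_ramp1
  for (e in seq_len(scheme$n_echoes)) {
    seg <- pol * g_amp * lobe
    g[i_lobe + seq_along(seg) - 1L] <- seg
    echo_center_idx[e] <- i_lobe + j_center - 1L
    t_center <- (echo_center_idx[e] - 1L) * dt
    st <- t_center - t_flat / 2 + dwell * (seq_len(nx) - 0.5)
    echo_samples[[e]] <- length(sample_times) + seq_len(nx)
    sample_times <- c(sample_times, st)
    if (e < scheme$n_echoes) {
      if (scheme$mode == "bipolar") {
        pol <- -pol
        i_lobe <- i_lobe + length(seg) + n_gap
      } else {
        # flyback rewinder: cancel the two half-lobes between echo centers
        rw <- trapezoid_lobe(-pol * 2 * a_half, n_gap, design, dt)
        rw_area <- pracma::trapz(seq_along(rw) * dt, rw)
        if (abs(rw_area) > 0) rw <- rw * (-pol * 2 * a_half / rw_area)
        g[i_lobe + length(seg) + seq_along(rw) - 1L] <- rw
        i_lobe <- i_lobe + length(seg) + n_gap
      }
    }
  }
  wf <- gradient_waveform(g, dt, axes = "r")
  attr(wf, "echo_center_idx") <- echo_center_idx
  attr(wf, "echo_samples") <- echo_samples
  attr(wf, "sample_times_s") <- sample_times
  attr(wf, "echo_parity") <- ifelse(seq_len(scheme$n_echoes) %% 2 == 1,
                                    "odd", "even")
  attr(wf, "kmax_grid") <- nx / 2
  attr(wf, "dwell_s") <- dwell
  attr(wf, "bw_per_pixel_hz_actual") <- 1 / t_flat
  attr(wf, "g_amp_mt_m") <- g_amp
  wf
}

# symmetric trapezoid (or triangle) of prescribed area within n_slots raster
# steps, respecting amplitude and slew limits; returns the sample vector
trapezoid_lobe <- function(area_mt_m_s, n_slots, design, dt) {
  if (n_slots < 2L) {
    if (abs(area_mt_m_s) < 1e-15) return(numeric(0))
    stop("no room for a rewinder/prephaser lobe")
  }
  a <- abs(area_mt_m_s)
  if (a < 1e-15) return(numeric(n_slots) * 0)
  s <- sign(area_mt_m_s)
  slew <- design$slew_max_t_m_s * 1e3 * 0.99          # mT/m per s
  gmax <- design$g_max_mt_m * 0.99
  # try triangle first: area = amp^2 / slew  -> amp = sqrt(area * slew)
  amp <- sqrt(a * slew)
  if (amp <= gmax) {
    n_ramp <- ceiling(amp / slew / dt)
    amp <- a / (n_ramp * dt)                           # exact-area triangle
    if (2L * n_ramp + 2L > n_slots) {
      n_ramp <- floor((n_slots - 2L) / 2)
      amp <- a / (n_ramp * dt)
    }
    if (n_ramp < 1L || amp > design$g_max_mt_m) {
      stop("lobe infeasible: amplitude limit")
    }
    ramp <- seq_len(n_ramp) / n_ramp
    lob <- s * amp * c(ramp, rev(ramp)[-1L], 0)
  } else {
    n_ramp <- ceiling(gmax / slew / dt)
    t_flat_needed <- (a - gmax * n_ramp * dt) / gmax
    n_flat <- ceiling(t_flat_needed / dt)
    amp <- a / ((n_ramp + n_flat) * dt)
    if ((2L * n_ramp + n_flat + 2L) > n_slots) stop("lobe infeasible: duration limit")
    ramp <- seq_len(n_ramp) / n_ramp
    lob <- s * amp * c(ramp, rep(1, n_flat), rev(ramp)[-1L], 0)
  }
  # leading zero keeps the assembled trapezoidal integral identical to the
  # isolated one (no half-sample leakage at the junction with the previous lobe)
  out <- numeric(n_slots)
  out[1L + seq_along(lob)] <- lob
  out
}

#' Per-spoke k-space sample positions
#'
#' Integrates the (optionally GIRF-distorted) readout waveform and maps it
#' onto each spoke direction, returning the k-space sample positions of every
#' echo. With a GIRF supplied, each physical axis is distorted independently,
#' so samples may leave the nominal spoke line.
#'
#' @param plan A [phyllotaxis_plan()] (or a matrix of unit directions).
#' @param readout A waveform from [build_readout()].
#' @param girf Optional `girf_model` for the actual-gradient prediction.
#' @param spokes Indices of spokes to evaluate (default: all).
#' @param system A [system_config()].
#' @param fov_m FOV (m) for grid-point units.
#' @param first_echo_calibration If `TRUE` (default) and a GIRF is supplied,
#'   a constant per-spoke k-space offset is removed so the first echo's mean
#'   sample error is zero, emulating the sequence's built-in first-echo
#'   calibration; later echoes keep their relative (parity-dependent) errors.
#' @return List with `k` (array n_samples x 3 x n_spokes, grid points),
#'   `echo_samples`, `echo_parity`, `sample_times_s`.
#' @export
spoke_kspace <- function(plan, readout, girf = NULL, spokes = NULL,
                         system = system_config(), fov_m = NULL,
                         first_echo_calibration = TRUE) {
  dirs <- if (inherits(plan, "phyllotaxis_plan")) plan$dir else plan
  if (is.null(spokes)) spokes <- seq_len(nrow(dirs))
  if (is.null(fov_m)) fov_m <- 0.22
  g_unit <- readout$G[, 1L]
  dt <- readout$dt
  sample_t <- attr(readout, "sample_times_s")
  echo_samples <- attr(readout, "echo_samples")
  n_out <- length(sample_t)
  karr <- array(0, dim = c(n_out, 3L, length(spokes)))
  t_raster <- (seq_along(g_unit) - 1) * dt
  for (si in seq_along(spokes)) {
    d <- dirs[spokes[si], ]
    G3 <- gradient_waveform(outer(g_unit, d), dt, c("x", "y", "z"))
    if (!is.null(girf)) {
      G3d <- apply_girf(G3, girf)
      traj <- integrate_trajectory(G3d, system, fov_m)
    } else {
      traj <- integrate_trajectory(G3, system, fov_m)
    }
    for (a in 1:3) {
      karr[, a, si] <- approx(t_raster, traj$k[, a], xout = sample_t,
                              rule = 2)$y
    }
    if (!is.null(girf) && isTRUE(first_echo_calibration)) {
      nom <- integrate_trajectory(G3, system, fov_m)
      idx1 <- echo_samples[[1L]]
      for (a in 1:3) {
        knom1 <- approx(t_raster, nom$k[, a], xout = sample_t[idx1],
                        rule = 2)$y
        karr[, a, si] <- karr[, a, si] - mean(karr[idx1, a, si] - knom1)
      }
    }
  }
  list(k = karr, echo_samples = echo_samples,
       echo_parity = attr(readout, "echo_parity"),
       sample_times_s = sample_t, spokes = spokes)
}
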