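#' Digital fat-water vial phantom
#'
#' Builds a multi-echo volume containing cylindrical vials of prescribed fat
#' fractions on a zero background, mirroring a physical water/oil emulsion
#' phantom (default reference fractions 0, 8.5, 20, 37, 63.2, 85.4, 92.1 and
#' 100%). Vials are laid out on a circle in-plane and extend through all
#' slices; an integer label map (0 = background, k = k-th vial) supports ROI
#' statistics.
#'
#' @param fractions Fat fractions per vial (%), each in `[0, 100]`.
#' @param shape Volume shape `(nx, ny, nz)`.
#' @param scheme An [echo_scheme()].
#' @param spectrum A [fat_spectrum()].
#' @param snr Optional SNR; if finite, complex Gaussian noise is added after
#'   normalization (the in-vitro vial SNRs ranged from about 7 to 43).
#' @param seed Noise seed.
#' @param r2star,phi0_deg,f0_hz Common tissue parameters for all vials.
#' @param system A [system_config()].
#' @return List with `volume` (a [multi_echo_volume()]) and `labels`
#'   (integer array `(nx, ny, nz)`).
#' @export
generate_vial_phantom <- function(fractions = c(0, 8.5, 20, 37, 63.2, 85.4,
                                                92.1, 100),
                                  shape = c(48, 48, 4),
                                  scheme = scheme_preset("bipolar3T"),
                                  spectrum = default_fat_spectrum(),
                                  snr = Inf, seed = 1L,
                                  r2star = 50, phi0_deg = 30, f0_hz = 0,
                                  system = system_config()) {
  if (any(fractions < 0 | fractions > 100)) stop("fractions must be in [0,100]")
  nv <- length(fractions)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  # vial centers on a circle; radius chosen from the layout
  ring_r <- 0.35 * min(nx, ny)
  vial_r <- min(0.45 * ring_r * sin(pi / max(nv, 2)), 0.12 * min(nx, ny))
  if (vial_r < 1) {
    stop("overlapping or sub-voxel vials at the requested shape; increase `shape`")
  }
  ang <- 2 * pi * (seq_len(nv) - 1) / nv
  cx <- nx / 2 + 0.5 + ring_r * cos(ang)
  cy <- ny / 2 + 0.5 + ring_r * sin(ang)
  labels <- array(0L, dim = c(nx, ny, nz))
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  plane <- matrix(0L, nx, ny)
  for (k in seq_len(nv)) {
    inside <- (xg - cx[k])^2 + (yg - cy[k])^2 <= vial_r^2
    if (any(plane[inside] != 0L)) stop("overlapping vials at the requested shape")
    plane[inside] <- k
  }
  for (z in seq_len(nz)) labels[, , z] <- plane

  te <- echo_times(scheme)
  ne <- length(te)
  sig_by_vial <- vapply(seq_len(nv), function(k) {
    v <- tissue_voxel(water = 1 - fractions[k] / 100, fat = fractions[k] / 100,
                      phi0_deg = phi0_deg, f0_hz = f0_hz, r2star = r2star)
    simulate_signal(v, spectrum, te, system)
  }, complex(ne))                                   # ne x nv
  data <- array(0i, dim = c(nx, ny, nz, ne))
  for (e in seq_len(ne)) {
    pe <- matrix(0i, nx, ny)
    for (k in seq_len(nv)) pe[plane == k] <- sig_by_vial[e, k]
    for (z in seq_len(nz)) data[, , z, e] <- pe
  }
  vol <- multi_echo_volume(data, te, meta = list(
    phantom = "vials", fractions = fractions, scheme = scheme$mode
  ))
  vol <- normalize_volume(vol)
  if (is.finite(snr)) vol <- add_complex_noise(vol, snr, seed)
  list(volume = vol, labels = labels)
}

#' Dynamic heart-like 2D phantom for the reconstruction demo
#'
#' Analytic phantom composed of circles: a static "body" disk, a pulsating
#' "heart" disk whose radius oscillates at the cardiac frequency, and a bulk
#' sinusoidal translation at the respiratory frequency. Because every
#' component has a closed-form Fourier transform, radial k-space data can be
#' evaluated exactly at arbitrary sample positions and times
#' (see [phantom_kspace()]), keeping data generation independent of any
#' reconstruction operator.
#'
#' @param fov_m Field of view (m).
#' @param resp_freq_hz Respiratory frequency (default 0.25 Hz).
#' @param card_freq_hz Cardiac frequency (default 1.2 Hz).
#' @param resp_amp_m Peak respiratory displacement along y (m).
#' @param card_amp_frac Fractional cardiac radius modulation of the heart disk.
#' @param water_only If `TRUE` all components are water (no chemical shift
#'   modulation across echoes); used by the trajectory-artifact experiment.
#' @return An object of class `dynamic_phantom` describing the components.
#' @export
generate_dynamic_phantom <- function(fov_m = 0.22, resp_freq_hz = 0.25,
                                     card_freq_hz = 1.2,
                                     resp_amp_m = 0.01, card_amp_frac = 0.25,
                                     water_only = TRUE) {
  comps <- data.frame(
    name = c("body", "heart", "blood"),
    cx = c(0, 0.02, 0.02) * fov_m / 0.22,
    cy = c(0, -0.01, -0.01) * fov_m / 0.22,
    radius = c(0.35, 0.14, 0.07) * fov_m / 2,
    amplitude = c(1, 0.8, -0.5),
    pulsatile = c(FALSE, TRUE, TRUE)
  )
  structure(
    list(components = comps, fov_m = fov_m, resp_freq_hz = resp_freq_hz,
         card_freq_hz = card_freq_hz, resp_amp_m = resp_amp_m,
         card_amp_frac = card_amp_frac, water_only = water_only),
    class = "dynamic_phantom"
  )
}

# motion state of the phantom at time t (s): displacement and radius scale
phantom_state <- function(ph, t) {
  list(
    dy = ph$resp_amp_m * sin(2 * pi * ph$resp_freq_hz * t),
    rscale = 1 + ph$card_amp_frac * 0.5 *
      (1 + cos(2 * pi * ph$card_freq_hz * t)) - ph$card_amp_frac * 0.5
  )
}

#' Analytic k-space of the dynamic phantom
#'
#' Exact Fourier transform of the phantom at given k-space positions and a
#' given acquisition time (motion is frozen within one readout). A uniform
#' disk of radius R at the origin transforms to
#' `2 pi R^2 jinc(2 pi R |k|)` with `jinc(x) = J1(x)/x`; translation and
#' dilation follow from the usual Fourier identities.
#'
#' @param ph A [generate_dynamic_phantom()].
#' @param k Matrix of k-space positions (n x 2, units 1/m).
#' @param t Acquisition time (s, scalar) for the motion state.
#' @return Complex vector of k-space samples.
#' @export
phantom_kspace <- function(ph, k, t = 0) {
  stopifnot(inherits(ph, "dynamic_phantom"))
  st <- phantom_state(ph, t)
  kr <- sqrt(k[, 1]^2 + k[, 2]^2)
  out <- complex(length(kr))
  for (i in seq_len(nrow(ph$components))) {
    co <- ph$components[i, ]
    R <- co$radius * if (co$pulsatile) st$rscale else 1
    cy <- co$cy + st$dy
    x <- 2 * pi * R * kr
    jinc <- ifelse(x < 1e-9, 0.5, besselJ(x, 1) / pmax(x, 1e-12))
    ft <- co$amplitude * 2 * pi * R^2 * jinc
    out <- out + ft * exp(-2i * pi * (k[, 1] * co$cx + k[, 2] * cy))
  }
  out
}

#' Rasterize the dynamic phantom onto an image grid
#'
#' Reference image for reconstruction benchmarks, evaluated at a given time.
#'
#' @param ph A [generate_dynamic_phantom()].
#' @param n Image matrix size.
#' @param t Time (s).
#' @param oversample Sub-pixel sampling factor for anti-aliased edges.
#' @return `n x n` numeric matrix.
#' @export
phantom_image <- function(ph, n, t = 0, oversample = 2L) {
  st <- phantom_state(ph, t)
  m <- n * oversample
  xs <- (seq_len(m) - (m + 1) / 2) / m * ph$fov_m
  img <- matrix(0, m, m)
  X <- matrix(xs, m, m)
  Y <- matrix(xs, m, m, byrow = TRUE)
  for (i in seq_len(nrow(ph$components))) {
    co <- ph$components[i, ]
    R <- co$radius * if (co$pulsatile) st$rscale else 1
    img <- img + co$amplitude *
      ((X - co$cx)^2 + (Y - (co$cy + st$dy))^2 <= R^2)
  }
  # box down-sample to n x n
  idx <- rep(seq_len(n), each = oversample)
  out <- rowsum(img, idx)
  out <- t(rowsum(t(out), idx)) / oversample^2
  out
}
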