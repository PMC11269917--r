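#' Tissue voxel parameters
#'
#' Ground-truth parameters of one voxel in the fat-water signal model:
#' water and fat magnitudes, common initial phase, B0 off-resonance and
#' effective transverse decay.
#'
#' @param water Water magnitude W (arbitrary units, >= 0).
#' @param fat Fat magnitude F (>= 0).
#' @param phi0_deg Common initial phase (degrees); holds for low flip angles.
#' @param f0_hz B0 off-resonance (Hz).
#' @param r2star Effective transverse decay R2* (1/s, >= 0), shared by water
#'   and fat.
#' @return An object of class `tissue_voxel`.
#' @examples
#' v <- tissue_voxel(water = 0.6, fat = 0.4, f0_hz = 40)
#' voxel_pdff(v)  # 40
#' @export
tissue_voxel <- function(water = 1, fat = 0, phi0_deg = 0, f0_hz = 0,
                         r2star = 0) {
  for (nm in c("water", "fat", "phi0_deg", "f0_hz", "r2star")) {
    stop_if_not_scalar_num(get(nm), nm)
  }
  if (water < 0 || fat < 0) stop("`water` and `fat` must be >= 0")
  if (r2star < 0) stop("`r2star` must be >= 0")
  structure(
    list(water = water, fat = fat, phi0_deg = phi0_deg, f0_hz = f0_hz,
         r2star = r2star),
    class = "tissue_voxel"
  )
}

#' Proton-density fat fraction of a voxel
#'
#' @param voxel A [tissue_voxel()].
#' @return PDFF in percent, `F / (W + F) * 100`; 0 when both magnitudes are 0.
#' @export
voxel_pdff <- function(voxel) {
  stopifnot(inherits(voxel, "tissue_voxel"))
  tot <- voxel$water + voxel$fat
  if (tot <= 0) return(0)
  100 * voxel$fat / tot
}

#' Net fat phasor of a spectrum at given times
#'
#' `c(t) = sum_m alpha_m exp(i 2 pi f_m t)`: the complex modulation of the
#' fat signal relative to water. Shared by the simulator and the fat-water
#' estimator basis.
#'
#' @param spectrum A [fat_spectrum()].
#' @param t Times (s).
#' @param system A [system_config()].
#' @return Complex vector, one value per time.
#' @export
fat_phasor <- function(spectrum, t, system = system_config()) {
  f <- peak_frequencies(spectrum, system)
  as.complex(exp(2i * pi * outer(t, f)) %*% spectrum$rel_amplitudes)
}

#' Simulate a noiseless multi-echo fat-water signal
#'
#' Evaluates the CSE signal model
#' `y(t) = (W + F * sum_m alpha_m e^{i w_m t}) * e^{i phi0} * e^{(i 2 pi f0 - R2*) t}`
#' at the requested echo times. Noise is added separately (see
#' [add_complex_noise()]).
#'
#' @param voxel A [tissue_voxel()].
#' @param spectrum A [fat_spectrum()].
#' @param echo_times_s Echo times in seconds (non-negative). An
#'   [echo_scheme()] may be passed instead.
#' @param system A [system_config()].
#' @return Complex vector, one sample per echo time; deterministic.
#' @examples
#' y <- simulate_signal(tissue_voxel(0.6, 0.4, f0_hz = 40, r2star = 50),
#'                      default_fat_spectrum(),
#'                      echo_times(scheme_preset("bipolar3T")))
#' Mod(y)
#' @export
simulate_signal <- function(voxel, spectrum, echo_times_s,
                            system = system_config()) {
  stopifnot(inherits(voxel, "tissue_voxel"), inherits(spectrum, "fat_spectrum"))
  if (inherits(echo_times_s, "echo_scheme")) {
    echo_times_s <- echo_times(echo_times_s)
  }
  if (any(echo_times_s < 0)) stop("echo times must be non-negative")
  ct <- fat_phasor(spectrum, echo_times_s, system)
  (voxel$water + voxel$fat * ct) *
    exp(1i * deg_to_rad(voxel$phi0_deg)) *
    exp((2i * pi * voxel$f0_hz - voxel$r2star) * echo_times_s)
}
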