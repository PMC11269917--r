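#' @useDynLib freerunfw, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft median quantile rnorm runif sd setNames
#' @importFrom utils head modifyList read.delim tail
NULL

# All internal computation uses SI units: times in seconds, frequencies in Hz,
# angles in radians, gradients in T/m, positions in m. Milliseconds, degrees,
# mT/m appear only at user-facing boundaries and are converted on entry.

ms_to_s <- function(x) x * 1e-3
s_to_ms <- function(x) x * 1e3
deg_to_rad <- function(x) x * pi / 180

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# polynomial rolling hash over a serialized R object; used for provenance
# blocks so outputs carry a fingerprint of the configuration that produced
# them (not cryptographic)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  # drop serialization header (R version dependent)
  bytes <- bytes[-seq_len(14L)]
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_block <- function(config = list(), seed = NULL) {
  list(
    package = "freerunfw",
    version = as.character(utils::packageVersion("freerunfw")),
    config_hash = config_hash(config),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' @noRd
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  dphi <- diff(phi)
  correction <- cumsum(round(-dphi / (2 * pi))) * 2 * pi
  phi + c(0, correction)
}
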