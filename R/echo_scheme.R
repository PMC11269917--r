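#' Multi-echo readout scheme
#'
#' Describes a gradient-echo readout polarity mode with its echo-time
#' arithmetic: `n_echoes` echoes at `te1 + k * dte`, all inside one
#' repetition time. Bipolar readouts alternate gradient polarity between
#' echoes (halving the achievable echo spacing); monopolar readouts use
#' same-polarity lobes with flyback rewinders.
#'
#' @param mode `"monopolar"` or `"bipolar"`.
#' @param n_echoes Number of echoes (>= 1).
#' @param te1_ms First echo time (ms).
#' @param dte_ms Echo spacing (ms, > 0).
#' @param tr_ms Repetition time (ms); the last echo must fall before it.
#' @return An object of class `echo_scheme`.
#' @examples
#' sch <- echo_scheme("bipolar", 13, 1.12, 1.07)
#' echo_times(sch)  # seconds
#' @export
echo_scheme <- function(mode = c("monopolar", "bipolar"), n_echoes, te1_ms,
                        dte_ms, tr_ms = 15) {
  mode <- match.arg(mode)
  stop_if_not_scalar_num(n_echoes, "n_echoes", positive = TRUE)
  stop_if_not_scalar_num(te1_ms, "te1_ms", positive = TRUE)
  stop_if_not_scalar_num(dte_ms, "dte_ms", positive = TRUE)
  stop_if_not_scalar_num(tr_ms, "tr_ms", positive = TRUE)
  n_echoes <- as.integer(n_echoes)
  last_te <- te1_ms + (n_echoes - 1) * dte_ms
  if (last_te >= tr_ms) {
    stop(sprintf("last echo time %.2f ms does not fit within TR %.2f ms",
                 last_te, tr_ms))
  }
  structure(
    list(mode = mode, n_echoes = n_echoes, te1_ms = te1_ms, dte_ms = dte_ms,
         tr_ms = tr_ms),
    class = "echo_scheme"
  )
}

#' Echo times of a scheme
#'
#' @param scheme An [echo_scheme()].
#' @param unit `"s"` (default, internal unit) or `"ms"`.
#' @return Strictly increasing numeric vector of echo times.
#' @export
echo_times <- function(scheme, unit = c("s", "ms")) {
  stopifnot(inherits(scheme, "echo_scheme"))
  unit <- match.arg(unit)
  te <- scheme$te1_ms + (seq_len(scheme$n_echoes) - 1) * scheme$dte_ms
  if (unit == "s") ms_to_s(te) else te
}

#' Named echo-scheme presets
#'
#' The two free-running CSE readout schemes used at 3T within a 15 ms TR:
#' `"monopolar3T"` with 8 echoes (TE1/dTE = 1.16/1.96 ms) and `"bipolar3T"`
#' with 13 echoes (TE1/dTE = 1.12/1.07 ms).
#'
#' @return Named list of [echo_scheme()] objects.
#' @export
scheme_presets <- function() {
  list(
    monopolar3T = echo_scheme("monopolar", 8L, 1.16, 1.96, 15),
    bipolar3T = echo_scheme("bipolar", 13L, 1.12, 1.07, 15)
  )
}

#' Look up an echo-scheme preset by name
#'
#' @param name `"monopolar3T"` or `"bipolar3T"`.
#' @return An [echo_scheme()].
#' @export
scheme_preset <- function(name) {
  presets <- scheme_presets()
  if (!name %in% names(presets)) {
    stop(sprintf("unknown scheme preset '%s' (available: %s)", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]
}

#' @export
print.echo_scheme <- function(x, ...) {
  cat(sprintf("<echo_scheme> %s: %d echoes, TE1 %.2f ms, dTE %.2f ms, TR %.0f ms\n",
              x$mode, x$n_echoes, x$te1_ms, x$dte_ms, x$tr_ms))
  invisible(x)
}
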