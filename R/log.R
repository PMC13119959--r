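# Lightweight leveled logging to stderr.
# Verbosity via options(biobattery.verbosity = "debug" | "info" | "warn" | "quiet").

.bb_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Package log message
#'
#' Emits a leveled message on stderr. The threshold is taken from
#' `options(biobattery.verbosity=)` ("debug", "info", "warn" or "quiet";
#' default "warn"). Clamp events, Nernst-floor activations and out-of-range
#' step sizes are reported through this channel.
#'
#' @param level One of "debug", "info", "warn".
#' @param ... Message parts, concatenated without separator.
#' @return Invisibly, `TRUE` if the message was emitted.
#' @export
bb_log <- function(level = "info", ...) {
  thr <- getOption("biobattery.verbosity", "warn")
  thr_i <- .bb_levels[[match.arg(thr, names(.bb_levels))]]
  lvl_i <- .bb_levels[[match.arg(level, c("debug", "info", "warn"))]]
  if (lvl_i >= thr_i) {
    message("[biobattery ", level, "] ", ...)
    invisible(TRUE)
  } else invisible(FALSE)
}
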