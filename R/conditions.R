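# Structured conditions. Every error raised by the package carries the class
# "npek_error" plus a specific subclass so callers can branch on failure mode.

#' @noRd
npek_stop <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "npek_error")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
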