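# Classed conditions so callers can distinguish failure modes programmatically.

stop_icu <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("icudischarge_", class), "icudischarge_error")))
}

warn_icu <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("icudischarge_", class), "icudischarge_warning")))
}
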