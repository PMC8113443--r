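# Classed conditions so callers can distinguish failure modes programmatically.
pt_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("placentatools_", class), "placentatools_error")))
}

pt_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) pt_stop(class, msg, ...)
  invisible(TRUE)
}
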