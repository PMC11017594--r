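# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., <class> = ...) instead of matching message strings.

mvc_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mvconsensus_error", "error", "condition")))
}

mvc_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) mvc_error(class, msg)
  invisible(TRUE)
}
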