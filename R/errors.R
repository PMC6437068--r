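# Classed conditions so callers can distinguish failure modes programmatically.

lip_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "lipidemt_error"), call = call))
}

lip_warn <- function(msg, class = "lipidemt_warning") {
  warning(warningCondition(msg, class = c(class, "lipidemt_warning")))
}
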