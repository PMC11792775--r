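# Classed conditions so callers can distinguish failure modes programmatically.

stop_moralassoc <- function(msg, class) {
  stop(structure(
    class = c(class, "moralassoc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format  <- function(msg) stop_moralassoc(msg, "moralassoc_format_error")
stop_empty   <- function(msg) stop_moralassoc(msg, "moralassoc_empty_error")
stop_missing_cue <- function(cue) {
  stop_moralassoc(sprintf("cue '%s' is not present in the association data", cue),
                  "moralassoc_missing_cue_error")
}
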