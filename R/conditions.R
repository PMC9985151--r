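# Classed error conditions used across the package.  Every error inherits
# from "rankindel_error" plus a specific class that tests can match on.

abort_ri <- function(message, class) {
  cond <- structure(
    class = c(class, "rankindel_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}
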