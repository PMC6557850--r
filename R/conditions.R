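# Structured error conditions so callers (and the CLI) can distinguish
# input-parsing problems from bad parameters, node lookups, ranking
# alignment, and statistics that are undefined on the given graph.

grStop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "gravityrankError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stopParse        <- function(msg, ...) grStop("gravityrankParseError", msg, ...)
stopParameter    <- function(msg, ...) grStop("gravityrankParameterError", msg, ...)
stopLookup       <- function(msg, ...) grStop("gravityrankLookupError", msg, ...)
stopAlignment    <- function(msg, ...) grStop("gravityrankAlignmentError", msg, ...)
stopUndefinedStat <- function(msg, ...) grStop("gravityrankUndefinedStatError", msg, ...)
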