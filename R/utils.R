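# internal string helpers

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# reverse complement of a base-call string; "-" and "N" are preserved under
# complementation ("-" -> "-", "N" -> "N"), order is reversed
revcomp_calls <- function(x) {
  comp <- chartr("ACGTN-", "TGCAN-", x)
  paste(rev(chars(comp)), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dogphen <- function(..., class = "dogphen_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
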