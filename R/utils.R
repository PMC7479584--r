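# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers can distinguish configuration mistakes,
# control-flow misuse, privacy violations and parse failures.
ef_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ef_error", "error", "condition")))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

# sample() without the length-1 surprise: always treats `x` as a vector of
# values, never as an upper bound.
sample_vec <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
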