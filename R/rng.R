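# Seeded RNG streams.
#
# Every session owns one stream and every simulated responder owns another,
# so the stimulus sequence and the simulated behaviour can be varied
# independently (re-running the same session seed with a different agent
# seed presents identical stimuli). A stream is an environment that carries
# a saved .Random.seed vector; each draw swaps it into the global
# environment, runs base RNG code, saves the advanced state back, and
# restores whatever RNG state the caller had. The caller's own random-number
# stream is therefore never perturbed by running a session.

rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0 ||
      seed != as.integer(seed)) {
    ef_stop("seed must be a single non-negative integer", "ef_config_error")
  }
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "ef_rng"
  e
}

rng_do <- function(rng, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

rng_sample <- function(rng, x, size = 1L, replace = FALSE) {
  rng_do(rng, function() sample_vec(x, size, replace))
}

rng_shuffle <- function(rng, x) {
  rng_do(rng, function() x[sample.int(length(x))])
}

rng_runif <- function(rng, n = 1L) {
  rng_do(rng, function() stats::runif(n))
}

# Lognormal response-time draw in whole milliseconds, strictly positive.
rng_rt_ms <- function(rng, median_ms, sigma) {
  rng_do(rng, function() {
    ms <- round(stats::rlnorm(1L, meanlog = log(median_ms), sdlog = sigma))
    max(1L, as.integer(ms))
  })
}
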