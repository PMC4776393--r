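# Seeded RNG streams that never disturb the caller's .Random.seed.
# A stream is an environment carrying its own generator state; draws swap the
# state in, evaluate, and swap back out. Sub-streams are derived by counter
# so per-embryo generation is reproducible independent of evaluation order.

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", s, envir = globalenv())
  }
}

.new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- .save_seed()
  set.seed(as.integer(seed %% 2147483647L))
  env$state <- get(".Random.seed", envir = globalenv())
  env$seed <- as.integer(seed %% 2147483647L)
  .restore_seed(old)
  env
}

# derive the i-th sub-stream of a stream by counter
.sub_rng <- function(rng, i) {
  .new_rng((as.double(rng$seed) * 48271 + as.double(i)) %% 2147483647)
}

.rng_eval <- function(rng, expr) {
  old <- .save_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .restore_seed(old)
  })
  expr
}

.rng_sample <- function(rng, n, size = n, replace = FALSE)
  .rng_eval(rng, sample.int(n, size = size, replace = replace))
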