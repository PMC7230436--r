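# internal helpers

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream-specific 31-bit sub-seed from a master seed
derive_seed <- function(seed, stream) {
  with_seed(seed, {
    offsets <- c(fixtures = 1L, panel = 2L, psa = 3L, general = 4L)
    if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
    (as.integer(seed) %% 100000L) * 13L + offsets[[stream]] * 7919L
  })
}
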