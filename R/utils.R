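# run code under a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# sample() without the length-1 surprise
sample_safe <- function(x, size) {
  x[sample.int(length(x), size)]
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)
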