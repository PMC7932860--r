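## Seeding helpers. All randomness in the package flows through withSeed()
## so callers' RNG state is never disturbed and identical seeds give
## bit-identical results.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Fixed counter scheme expanding one base seed into per-item seeds, kept
## below 2^31 so they remain valid R integers.
deriveSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 8191) %% 2147483629)
}

## Conventional half-up rounding (round() in R is banker's rounding).
roundHalfUp <- function(x) floor(x + 0.5)

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
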