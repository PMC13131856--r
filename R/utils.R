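# Internal helpers: seed substreams and argument checks.

# Derive a reproducible sub-seed from a master seed and a stream label, so
# that each generator (genotypes, latent noise, rendering, traits, ...) can be
# re-run independently of the others. Keeps the result inside 32-bit range.
subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483563) + 1L
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# column standardization (mean 0, sd 1 with denominator n-1)
standardizeCols <- function(x) {
  x <- as.matrix(x)
  cm <- colMeans(x)
  cs <- apply(x, 2L, stats::sd)
  cs[cs == 0] <- 1
  sweep(sweep(x, 2L, cm, "-"), 2L, cs, "/")
}
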