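## Internal helpers: local RNG scope and sub-seed derivation.

## Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
## With seed = NULL the expression runs on the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive `n` reproducible sub-seeds (< 2^31) from a master seed, one named
## stream per pipeline stage so stages can be replayed independently.
deriveSeeds <- function(seed, n, stage = "stage") {
  offset <- sum(utf8ToInt(stage)) * 1009L
  withSeed(if (is.null(seed)) NULL else (as.integer(seed) + offset) %% .Machine$integer.max,
           sample.int(.Machine$integer.max - 1L, n))
}

## uniform-grid check used by the detectors
assertUniformTimes <- function(times) {
  if (length(times) < 3L)
    stop("at least 3 time points are required")
  d <- diff(times)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8 * max(abs(d)))
    stop("time points must be strictly increasing and uniformly spaced")
  invisible(d[1])
}

fmtNum <- function(x) signif(x, 6)
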