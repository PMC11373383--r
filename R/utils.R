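#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation.  Mixes a master seed with one or more
# stream indices so that every replicate / run / epoch draws from its own
# reproducible stream.  Result always lies in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.double(seed %% m)
  for (i in idx) {
    # Carter-Wegman style multiply-add hash; doubles hold these exactly.
    s <- (s * 48271 + as.double(i) * 16807 + 1) %% m
  }
  as.integer(s %% (m - 2)) + 1L
}

# Round a double vector through IEEE-754 single precision, the precision at
# which DAF and distance values are stored on disk.
as_float32 <- function(x) {
  readBin(writeBin(as.double(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

# Run an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
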