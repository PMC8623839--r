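# Internal helpers: reproducible local RNG scoping and seed derivation.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream.  All stochastic package functions route their randomness through
# this, so identical (config, seed) inputs give bit-identical output.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Mix a base seed with stream identifiers (subject, session, purpose tags)
# into a single integer seed < 2^31.  Exact in double arithmetic.
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 1000003 + (as.numeric(p) %% 1013904223)) %% 2147483647
  }
  as.integer(h)
}

# Daubechies decomposition filters (standard orthonormal coefficients).
db_filters <- function(wavelet = "db7") {
  lo <- switch(wavelet,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079, 0.48296291314453416),
    db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    db7 = c(0.00035371379997452024, -0.0018016407040474908,
            0.0004295779729213665, 0.01255099855609984, -0.01657454163066688,
            -0.03802993693501441, 0.08061260915108308, 0.07130921926683026,
            -0.22403618499387498, -0.14390600392856498, 0.4697822874051931,
            0.7291320908462351, 0.3965393194819173, 0.07785205408500918),
    stop("unknown wavelet: ", wavelet)
  )
  n <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(n)
  list(lo = lo, hi = hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
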