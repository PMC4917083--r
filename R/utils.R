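#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  code
}

# 32-bit helpers on the unsigned-double representation [0, 2^32)
mul32 <- function(a, b) {
  hi <- (a %/% 65536) * b
  ((hi %% 65536) * 65536 + (a %% 65536) * b) %% 4294967296
}
xor32 <- function(a, b) {
  s <- function(u) as.integer(u - (u >= 2147483648) * 4294967296)
  u <- bitwXor(s(a), s(b))
  u + (u < 0) * 4294967296
}

# MurmurHash3 32-bit finalizer: full avalanche, so nearby inputs map to
# effectively independent outputs
fmix32 <- function(x) {
  x <- xor32(x, x %/% 65536)
  x <- mul32(x, 2246822507)
  x <- xor32(x, x %/% 8192)
  x <- mul32(x, 3266489909)
  xor32(x, x %/% 65536)
}

#' Derive a deterministic per-unit substream seed
#'
#' Maps a master seed and a unit index to a 31-bit seed through an
#' avalanche-quality integer hash, so derived substreams are mutually
#' uncorrelated even for structured (seed, index) lattices, and a unit's
#' draws depend only on its own (seed, index) pair.
#'
#' @param seed master integer seed.
#' @param index positive unit index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, index) {
  h <- fmix32((abs(as.double(seed)) + mul32(as.double(index) %% 4294967296,
                                            2654435761)) %% 4294967296)
  h <- fmix32(xor32(h, as.double(index) %% 4294967296))
  as.integer(h %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)
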