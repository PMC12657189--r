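#' @keywords internal
"_PACKAGE"

# Run code with a temporarily seeded RNG, restoring global state afterwards.
# All stochastic entry points route through this so a single integer seed
# reproduces every result bit-for-bit.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream index; keeps every
# sub-stream inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a hash over the serialized object; used for bit-identity checksums of
# parameter sets (e.g. the freeze contract) without external digest libraries.
params_checksum <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 3L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stopifnot_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", nm), call. = FALSE)
  }
}
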