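# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("invalid field 'seed': must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# FNV-1a hash of a character scalar, returned as 8 hex digits.  Used only to
# stamp output files with a config fingerprint, so collisions are harmless.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); h itself can exceed 2^31,
    # so do the xor on the extracted byte rather than the full word
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619; split into 16-bit
    # halves so intermediate products stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # format as hex from the 16-bit halves (%x needs integers)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config), collapse = "\n"))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
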