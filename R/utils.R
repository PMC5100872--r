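# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
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

# sample() interprets a length-1 numeric first argument as 1:n; this picks
# uniformly from the vector itself regardless of its length.
sample_one <- function(x) x[sample.int(length(x), 1L)]

sample_exact <- function(x, size) {
  if (size > length(x)) stop("cannot sample ", size, " items from ", length(x))
  x[sample.int(length(x), size)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit polynomial rolling hash of a character vector; used only to stamp
# outputs with a config fingerprint for provenance.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

stop_fatal <- function(...) stop(..., call. = FALSE)
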