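# Internal helpers: error signalling, seeded RNG scopes, content digests.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("spinmaps_invalid_argument", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("spinmaps_format_error", "error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("spinmaps_numerical_error", "error")))
}

stop_insufficient <- function(...) {
  stop(errorCondition(paste0(...), class = c("spinmaps_insufficient_data", "error")))
}

stop_unsupported <- function(...) {
  stop(errorCondition(paste0(...), class = c("spinmaps_unsupported_transform", "error")))
}

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop_invalid("'seed' must be a single integer, got: ", deparse(seed))
  }
  as.integer(seed)
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# All randomness in the package flows through this, so any object is a pure
# function of its (inputs, seed).
with_seed <- function(seed, expr) {
  seed <- assert_seed(seed)
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
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a stream of child seeds from one master seed. Capped at 2^30 so
# callers can add small offsets without risking 32-bit integer overflow.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(1073741824L, n, replace = FALSE))
}

# Content digest of arbitrary R objects via base R only: serialize to a
# tempfile and md5 it.  Used for cache keys and provenance.
content_digest <- function(x) {
  path <- tempfile(fileext = ".bin")
  on.exit(unlink(path))
  con <- file(path, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
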