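# Internal helpers: seeded evaluation, seed derivation, error classes.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic child seed from a base seed and stream indices
#'
#' Mixes the base seed with any number of integer indices (round, bootstrap,
#' client, ...) into a new seed in `[0, 2^31 - 2]`, so every randomised step
#' of a federation draws from its own reproducible stream.
#'
#' @param base_seed Integer base seed.
#' @param ... Integer stream indices.
#' @return An integer seed.
#' @export
derive_seed <- function(base_seed, ...) {
  parts <- c(as.numeric(base_seed), as.numeric(unlist(list(...))))
  primes <- c(1, 7919, 104729, 1299709, 15485863)
  acc <- 0
  for (i in seq_along(parts)) {
    p <- primes[((i - 1) %% length(primes)) + 1]
    acc <- (acc + (parts[i] %% 2147483647) * p) %% 2147483647
  }
  as.integer(acc)
}

stop_fedbids <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "fedbids_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# md5 of an existing file (used for cache keys).
file_md5 <- function(path) unname(tools::md5sum(path.expand(path)))

# md5 of an arbitrary R object via canonical serialization to a temp file.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  file_md5(f)
}
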