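#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points route their
# randomness through this so that a fixed seed gives bit-identical output
# regardless of surrounding RNG use.
with_local_seed <- function(seed, code) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621) %% 2147483399) + 1L
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

stop_dim <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
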