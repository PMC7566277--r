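# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed for a named pipeline stage, derived from the master
# seed. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, counts = 23L, rarefy = 37L, nmds = 53L,
    indicators = 71L, dbrda = 89L, noise = 101L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage name: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + off
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop(name, " must be >= 0", call. = FALSE)
  invisible(x)
}
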