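#' @keywords internal
"_PACKAGE"

# Largest prime below 2^31; all derived seeds stay in [0, 2^31 - 2] so they
# are valid R integer seeds.
.SEED_MOD <- 2147483647

#' Derive a stable sub-seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer stream
#' identifiers (for example a user index, or an experiment counter) so that
#' every source of randomness in the package can be traced back to a single
#' master seed without correlated streams.
#'
#' @param seed Master integer seed.
#' @param ... Integer stream identifiers, mixed in order.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' mix_seed(7, 1)
#' mix_seed(7, 1, 2)
mix_seed <- function(seed, ...) {
  parts <- c(...)
  a <- as.numeric(seed) %% .SEED_MOD
  for (p in parts) {
    # multiplier 48271 (Lehmer); products stay below 2^53 so %% is exact
    a <- (a * 48271 + as.numeric(p) * 9973 + 17) %% .SEED_MOD
  }
  as.integer(a)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
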