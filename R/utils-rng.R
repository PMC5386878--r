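#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from a single integer seed.  Each
#' generator draws from its own named substream so that adding or reordering
#' generators does not perturb the output of the others.  The substream seed
#' is a deterministic hash of the master seed and the stream name, kept below
#' 2^31 so it is always a valid R integer.
#'
#' @param seed integer master seed.
#' @param name character stream name, e.g. `"species_tree"`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substreamSeed(1, "species_tree")
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  # multipliers kept small enough that doubles stay exact (< 2^53)
  as.integer((abs(seed) %% m * 69621 + h * 8121 + 28411) %% m)
}

# Run `code` under a substream of `seed` without disturbing the caller's RNG.
withSubstream <- function(seed, name, code) {
  withr::with_seed(substreamSeed(seed, name), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
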