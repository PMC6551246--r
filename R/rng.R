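#' Derive a reproducible substream seed
#'
#' All randomness in rarecell flows from explicit integer seeds. A single
#' master seed is expanded into independent named substreams (gene means,
#' marker selection, fold changes, library sizes, counts, per-backend
#' clustering, per-replicate grid cells) so that adding a simulation step
#' never perturbs the draws of an earlier one.
#'
#' The derivation is a plain polynomial rolling hash of the master seed and
#' the stream tokens, reduced modulo 2^31 - 1. It is stable across platforms
#' and R versions (integer arithmetic only, no serialization involved).
#'
#' @param master_seed non-negative integer master seed.
#' @param ... further tokens (coerced to character) naming the substream.
#' @return A single integer in `[1, 2^31 - 2]`, suitable for `set.seed()`.
#' @examples
#' substream_seed(1, "means")
#' substream_seed(1, "counts", 3L) # replicate-specific stream
#' @export
substream_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed), master_seed >= 0)
  tokens <- paste(c(format(master_seed, scientific = FALSE),
                    vapply(list(...), as.character, character(1))),
                  collapse = "/")
  h <- 0
  for (b in utf8ToInt(tokens)) {
    # stays below 2^53, so exact in double arithmetic
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so substreams cannot leak into each other.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
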