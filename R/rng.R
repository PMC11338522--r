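#' Derive a reproducible seed for a named substream
#'
#' Folds a master seed and an arbitrary sequence of labels (numbers or
#' strings) into a single 31-bit seed with a multiplicative hash. Replicate
#' images, groups and acceptance targets each get their own substream so that
#' simulations can be regenerated piecewise without replaying a single global
#' generator state.
#'
#' @param master Integer master seed.
#' @param ... Stream labels: integers or character scalars.
#' @return A single integer in `[1, 2^31 - 20]`, suitable for [set.seed()].
#' @examples
#' seed_stream(42, "control", 3)
#' @export
seed_stream <- function(master, ...) {
  parts <- list(master, ...)
  h <- 0
  for (p in parts) {
    stopifnot(length(p) == 1L)
    v <- if (is.character(p)) {
      cp <- utf8ToInt(p)
      sum(cp * seq_along(cp)) %% 2147483629
    } else {
      as.numeric(p) %% 2147483629
    }
    # 48271 * 2^31 < 2^53: exact in double arithmetic
    h <- (h * 48271 + v + 11) %% 2147483629
  }
  as.integer(h) + 1L
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
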