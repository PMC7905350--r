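# Internal helpers: scoped RNG use so user-facing functions taking an explicit
# seed never disturb the caller's RNG state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seeds below 2^31, derived from a base seed and a
# few small integer tags (subject index, state, fold, ...).
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 48271 + as.double(t) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

#' Parameter count of a fully connected feed-forward network
#'
#' Weights plus biases of a dense multilayer perceptron, e.g. a 320-30-1
#' architecture carries `320*30 + 30 + 30*1 + 1 = 9661` trainable parameters.
#' Useful when comparing the sparse RBF classifier against dense baselines.
#'
#' @param layers Integer vector of layer widths, input first, output last.
#' @return Total number of weight and threshold (bias) parameters.
#' @export
#' @examples
#' dense_param_count(c(320, 30, 1))  # 9661
dense_param_count <- function(layers) {
  layers <- as.integer(layers)
  stopifnot(length(layers) >= 2L, all(layers >= 1L))
  sum(layers[-length(layers)] * layers[-1L]) + sum(layers[-1L])
}
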