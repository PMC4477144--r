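#' @importFrom stats sd runif plogis rbinom quantile
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Derive a deterministic stream of sub-seeds from one master seed without
# touching the caller's RNG state. Values stay below 2^31 so they are valid
# R integer seeds.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Canonical stimulus class labels
#'
#' The seven stimulus classes of the generalization test, ordered from the
#' prototype through increasing distortion levels to the random foils.
#'
#' @return Character vector of length 7.
#' @export
stimulus_classes <- function() {
  c("prototype", "L2", "L3", "L4", "L5", "L7", "random")
}

# distortion levels usable for training/test distortions
distortion_levels <- function() c("L2", "L3", "L4", "L5", "L7")

# canonical per-class trial counts of the 60-item test
test_class_counts <- function() {
  c(prototype = 5L, L2 = 5L, L3 = 5L, L4 = 5L, L5 = 5L, L7 = 5L, random = 30L)
}
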