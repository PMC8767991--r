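#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rbinom rnbinom runif setNames uniroot
#' @importFrom utils head
NULL

# package-local cache (default hierarchy, fitted count law)
the <- new.env(parent = emptyenv())

round2 <- function(x) round(x, 2)

# deterministic child seeds below 2^31, derived from one user seed
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% .Machine$integer.max
}

is_count <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))
}
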