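# Internal helpers shared across modules.

#' @importFrom stats median rbinom rlnorm rnbinom rpois runif sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. A NULL seed runs the code as-is.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a sub-seed for an internal stage so that, e.g.,
# changing the number of permutations never perturbs the simulator stream.
# Kept below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
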