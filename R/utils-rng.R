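#' Derive a reproducible sub-stream seed
#'
#' Each stochastic stage of the pipeline draws from its own RNG stream, derived
#' deterministically from a master seed and a stage label. This makes partial
#' reruns (e.g. regenerating clinical scores without regenerating maps)
#' reproducible: the stream a stage sees does not depend on how many draws
#' earlier stages consumed.
#'
#' @param seed Integer master seed.
#' @param label Character stage label, e.g. `"phenotypes"`.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(42, "phenotypes")
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps the result a valid R integer
  h <- abs(as.double(seed)) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under the sub-stream RNG state, restoring the caller's state.
with_substream <- function(seed, label, expr) {
  withr::with_seed(substream_seed(seed, label), expr)
}

# Shared input checkers ------------------------------------------------------

stop_invalid <- function(problems, what) {
  stop(sprintf("invalid %s: %s", what, paste(problems, collapse = "; ")),
       call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)
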