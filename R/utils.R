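#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test lm lm.fit median optimize pbinom
#'   pchisq qchisq quantile rbinom rlnorm rnorm runif sd setNames var
#'   mahalanobis complete.cases fft nextn chisq.test aggregate
#' @importFrom utils write.csv read.csv head tail
NULL

# run expr with a temporary RNG state seeded from `seed`; restores state after
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# derive a stream of child seeds from a master seed (keeps values < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 0

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a probability in [0, 1]", name)
  invisible(x)
}
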