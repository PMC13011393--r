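#' @useDynLib betanull, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dist rlnorm rmultinom rnorm runif sd rbinom
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic stream splitting: every exported stochastic function takes an
## explicit seed; internal stages derive child seeds from it so that no stage
## consumes another stage's stream. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(k)) %% 2147483629)
}

assert_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
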