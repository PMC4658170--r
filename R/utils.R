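#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the conventional half-up rule so that e.g. 25.615 -> 25.62 at two decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(x) {
  nzchar(x) & !grepl("[^ACGTN]", x)
}

stop_data <- function(...) stop(..., call. = FALSE)

## Derive a stream-specific seed from a master seed, staying inside the
## 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97L * offset) %% .Machine$integer.max)
}
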