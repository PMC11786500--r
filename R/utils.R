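## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Plain decimal rounding where .5 always rounds up, as spreadsheet software
#' does; `base::round()` rounds half to even, which would not reproduce
#' reported category percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

## Zero-truncated Poisson sampler (inverse-CDF on the truncated tail).
## `lambda` is the mean of the underlying (untruncated) Poisson.
rztpois <- function(n, lambda) {
  stopifnot(lambda > 0)
  if (n == 0L) return(integer(0))
  p0 <- dpois(0, lambda)
  pmax(1L, qpois(p0 + runif(n) * (1 - p0), lambda))
}

## Random fixed-length sequences over the DNA alphabet.
rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

## Barcode/UMI strings must be non-empty and must not contain characters
## that would break the tab-separated dialect.
is_valid_tag <- function(x) {
  nzchar(x) & !grepl("[[:space:]]", x)
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}
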