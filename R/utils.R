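#' Round half away from zero
#'
#' Report-style rounding: 0.05 at the last kept digit always rounds up,
#' matching how the summary tables print percentages (one decimal).
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## log(sum(exp(lx))) without overflow; lx may contain -Inf
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## percentage with one-decimal half-up rounding (Table-style reporting)
pct1 <- function(num, den) {
  if (den == 0) return(0)
  round_half_up(100 * num / den, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample() that never treats a length-1 vector as 1:n
resample <- function(x, n = length(x), ...) x[sample.int(length(x), n, ...)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]
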