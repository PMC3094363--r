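#' Round half away from zero
#'
#' Rounding used for reported integer percents: ties go away from zero
#' (so 90.5 -> 91), unlike [base::round()]'s round-half-even. Full precision
#' is retained internally everywhere; this is presentation-layer rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(90.5)  # 91
#' round_half_away(-2.5)  # -3
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# scalar check helpers used by validators
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
is_chr1 <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
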