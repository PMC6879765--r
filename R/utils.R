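#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed report tables in this field
#' round half away from zero (0.45 -> 0.5). Used only at rendering time —
#' all internal arithmetic keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.45, -0.45, 2.675), 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values like 2.675 stored as 2.67499...
  # still round up as their decimal literal intends
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# shared token normalisation for sex annotations
normalize_sex <- function(x) {
  out <- rep(NA_character_, length(x))
  low <- tolower(trimws(as.character(x)))
  out[low %in% c("female", "f")] <- "female"
  out[low %in% c("male", "m")] <- "male"
  out
}

sex_levels <- c("female", "male")

valid_chroms <- c(as.character(1:22), "X", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a
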