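#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Round a value for table display
#'
#' Decimal rounding used by all report writers. Values are first snapped to
#' `digits + 6` decimals to strip floating-point accumulation noise (so that,
#' e.g., a column mean that is an exact decimal half is treated as one), then
#' rounded half-to-even at `digits` decimals. Internal computations always
#' carry full precision; this function only affects display and printed
#' tables.
#'
#' @param x numeric vector.
#' @param digits number of decimals to keep (default 2).
#' @return numeric vector rounded for display.
#' @export
#' @examples
#' round_display(1.125)  # 1.12
#' round_display(4.876)  # 4.88
round_display <- function(x, digits = 2) {
  round(round(x, digits + 6), digits)
}

# stop() with sprintf formatting and no call in the message
pe_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

# Derive a child seed from a master seed; keeps results < 2^31 so they are
# valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647) * 1103 + 7919 * offset) %% 2147483647L
}

hash_text <- function(x) {
  rlang::hash(paste(x, collapse = "\n"))
}

hash_file <- function(path) {
  rlang::hash(readBin(path, "raw", n = file.size(path)))
}
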