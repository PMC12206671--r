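#' Round half away from zero ("round half up" for non-negative values)
#'
#' All integer counts, percentages and minute totals reported by this package
#' use a single rounding convention: the exact ratio is computed once and then
#' rounded with ties going upward (0.5 -> 1), never R's banker's rounding and
#' never chained through intermediate rounded values.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(100 * 3646 / 17293)  # 21
#' round_half_up(20.5)                # 21
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Percentage with the package rounding convention; NA (undefined) when the
# denominator is zero rather than an error or Inf.
pct_of <- function(part, whole, digits = 0) {
  whole <- rep_len(whole, length(part))
  ifelse(whole == 0, NA_real_, round_half_up(100 * part / whole, digits))
}

config_error <- function(msg, field = NULL) {
  stop(rlang::error_cnd(
    class = "telealert_config_error",
    message = if (is.null(field)) msg else sprintf("%s [field: %s]", msg, field)
  ))
}

data_error <- function(msg) {
  stop(rlang::error_cnd(class = "telealert_data_error", message = msg))
}

contract_error <- function(msg) {
  stop(rlang::error_cnd(class = "telealert_contract_error", message = msg))
}

# ISO weekday, Monday = 1 ... Sunday = 7.
iso_weekday <- function(date) as.integer(format(date, "%u"))

MEASUREMENT_SLOTS <- c("morning-1", "morning-2", "evening-1", "evening-2")

measurement_id <- function(user_id, date, slot) {
  paste(user_id, format(date), slot, sep = ":")
}
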