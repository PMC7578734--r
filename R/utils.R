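# Internal numeric helpers.
#
# All published statistics are ratios of small integer counts, so rounding is
# done on the exact rational (num/den) rather than on an already-rounded
# double: half-up at the displayed precision, e.g. 405/400 -> 1.01 at two
# decimals and 25/130 -> 19.2% at one decimal.

# Round num/den half-up to `digits` decimals using integer arithmetic.
# Vectorised over num/den. Counts in this package are tiny (<= a few
# thousand), so doubles hold the scaled integers exactly.
round_half_up_ratio <- function(num, den, digits = 2L) {
  stopifnot(all(den > 0))
  scale <- 10^digits
  floor((2 * num * scale + den) / (2 * den)) / scale
}

# Percentage num/den * 100, rounded half-up.
pct_ratio <- function(num, den, digits = 2L) {
  round_half_up_ratio(100 * num, den, digits)
}

# Deterministic key for an itemset: sorted codes joined by ",".
itemset_key <- function(items) {
  paste(sort.int(items, method = "radix"), collapse = ",")
}

split_key <- function(key) strsplit(key, ",", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a
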