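# internal helpers shared across modules

# stopifnot() with a formatted message
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

.is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# trapezoid-rule integral of y over (not necessarily uniform) grid x
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# cumulative trapezoid integral, same length as x, starting at 0
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# derive a stream-specific 32-bit sub-seed from a master seed
.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 1013) %% 2147483647)
}
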