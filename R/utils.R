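# internal helpers shared across modules

# half-up rounding (base round() is round-half-even); used for printed percents
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# right-continuous step-function evaluation with value `left` before the
# first knot and last-value-carried-forward beyond the last knot
step_eval <- function(x, y, xout, left = 1) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(rep(left, length(xout)))
  idx <- findInterval(xout, x)
  out <- c(left, y)[idx + 1L]
  out
}

is_binary01 <- function(x) {
  v <- unique(x[!is.na(x)])
  length(v) <= 2L && all(v %in% c(0, 1))
}

# numeric coding of a mixed-type column for correlation screens and chain
# statistics: factors/characters -> integer codes, logicals -> 0/1
num_code <- function(x) {
  if (is.factor(x)) as.numeric(x)
  else if (is.character(x)) as.numeric(factor(x))
  else as.numeric(x)
}
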