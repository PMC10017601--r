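# Internal helpers shared across modules.

#' @keywords internal
fcd_stop <- function(...) stop(..., call. = FALSE)

# Round half away from zero, as tables in clinical journals are printed.
# base::round() rounds half to even, which would misplace band edges.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Validate a vector of wall scores (ordinal 0..3).
check_wall_score <- function(x, field) {
  if (length(x) == 0L) fcd_stop(sprintf("'%s' must be non-empty", field))
  if (anyNA(x) || !is.numeric(x) || any(x != as.integer(x)) ||
      any(x < 0L) || any(x > 3L)) {
    fcd_stop(sprintf("'%s' must contain integer wall scores in {0, 1, 2, 3}",
                     field))
  }
  as.integer(x)
}

check_cutoff <- function(cutoff) {
  if (length(cutoff) != 1L || anyNA(cutoff) || cutoff != as.integer(cutoff) ||
      cutoff < 0L || cutoff > 7L) {
    fcd_stop("'cutoff' must be a single integer in 0..7")
  }
  as.integer(cutoff)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Ratio guarded against zero denominators: returns NA_real_ and lets the
# caller flag the metric as undefined rather than propagating NaN.
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

fmt_stat <- function(x) formatC(x, digits = 3, format = "f")
fmt_pct <- function(x) formatC(100 * x, digits = 1, format = "f")
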