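# Shared internal helpers.

# Round half away from zero at `digits` decimals, as report tables are
# conventionally printed (base round() ties to even).  The 1e-9 nudge
# keeps values that are exactly representable ties (e.g. 0.125 printed
# at 2 decimals) from falling on the wrong side of floating error.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Integer truncation with a small absolute guard so that products that
# are integers in exact arithmetic (e.g. 6 * 4/12 * 38^2) are not pushed
# below the integer by floating error.
floor_guard <- function(x) floor(x + 1e-9)

# Group labels: trim surrounding whitespace; blank or missing labels
# fall into an explicit "(ungrouped)" bucket.
normalize_group <- function(group) {
  g <- trimws(as.character(group))
  g[is.na(g) | g == ""] <- "(ungrouped)"
  g
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == trunc(x)
}

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
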