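# internal helpers shared across modules

# half-up rounding to `digits` decimals; base round() is half-even, while the
# study tables report percentages rounded half-up to one decimal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# match.arg with a friendlier error for user-facing enums
check_enum <- function(value, choices, arg = deparse(substitute(value))) {
  if (length(value) != 1L || !is.character(value) || !value %in% choices) {
    abort(sprintf(
      "`%s` must be one of %s, not %s.",
      arg, paste0('"', choices, '"', collapse = ", "),
      if (is.character(value)) paste0('"', value, '"') else class(value)[1]
    ))
  }
  value
}

check_number <- function(value, arg = deparse(substitute(value)),
                         min = -Inf, strict_min = FALSE) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value)) {
    abort(sprintf("`%s` must be a single finite number.", arg))
  }
  bad <- if (strict_min) value <= min else value < min
  if (bad) {
    abort(sprintf(
      "`%s` must be %s %s.", arg, if (strict_min) ">" else ">=", format(min)
    ))
  }
  as.numeric(value)
}

# condition with a dedicated class so the pipeline manifest can harvest it
lift_warn <- function(msg, class) {
  warn(msg, class = c(class, "liftrisk_warning"))
}

# derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 69069 + as.double(k) * 101 + 1) %% 2147483647
  as.integer(s)
}

channel_names <- function() c("ax", "ay", "az", "vx", "vy", "vz")
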