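#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_field(field, "must be a single probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_number <- function(x, field, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop_field(field, sprintf("must be a single finite number >= %s", format(min)))
  }
  invisible(as.numeric(x))
}

# Round half away from zero at `digits` decimals (matches how clinical tables
# are typically typeset; base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible sub-seed from a master seed and a stream label, so each
# generator draws from its own stream without coupling to the others.
substream_seed <- function(seed, label) {
  h <- utils::head(utf8ToInt(label), 16L)
  acc <- as.numeric(seed %% 2147483647L)
  for (k in h) acc <- (acc * 31 + k) %% 2147483647
  as.integer(acc)
}
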