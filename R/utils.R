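# internal validation and seeding helpers

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max),
          class = "herbnet_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != trunc(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "herbnet_config_error")
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a fraction in [0, 1]", name),
          class = "herbnet_config_error")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame", what), class = "herbnet_input_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "herbnet_input_error")
  }
  invisible(df)
}

# Derive a reproducible 32-bit sub-seed from a root seed and a stream label,
# so each synthetic table draws from its own named substream.
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 10007 + h) %% 2147483629)
}

with_substream <- function(seed, stream, code) {
  withr::with_seed(substream_seed(seed, stream), code)
}
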