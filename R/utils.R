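# Internal helpers shared across modules.

# Scalar checks ---------------------------------------------------------

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_na = FALSE, integerish = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name),
          class = "chimerase_config_error")
  }
  if (integerish && x != trunc(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "chimerase_config_error")
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x)),
          class = "chimerase_config_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", name),
          class = "chimerase_config_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste(missing, collapse = ", ")),
          class = "chimerase_config_error")
  }
  invisible(df)
}

# Error constructors used throughout: configuration errors are caller
# mistakes (bad thresholds, missing samples); estimation errors mean the
# data cannot support the requested estimate; parse errors point at input
# records.

config_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "chimerase_config_error")
}

estimation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "chimerase_estimation_error")
}

parse_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "chimerase_parse_error")
}

origin_levels <- c("O_ONLY", "C_ONLY", "BOTH", "UNINFORMATIVE")
layer_levels <- c("L1_SPECIFIC", "L2L3_SPECIFIC", "SHARED", "UNCLASSIFIED")
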