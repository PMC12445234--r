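# internal helpers shared across modules

# Deterministic per-stage substream of a master seed. Keeps every stage's
# stream independent while staying inside 32-bit integer range.
substream_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) * 7919 + h * 104729) %% 2147483587L + 1L)
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# percentile with a named estimator; "linear" interpolates between order
# statistics (quantile type 7), "nearest_rank" takes the ceiling(n*p)-th
# order statistic (quantile type 1)
percentile_value <- function(x, p, method = c("linear", "nearest_rank")) {
  method <- match.arg(method)
  type <- if (method == "linear") 7L else 1L
  unname(quantile(x, probs = p, type = type, names = FALSE))
}
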