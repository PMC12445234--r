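#' Percent body-weight change across the stressor
#'
#' `100 * (weight_day1 - weight_day0) / weight_day0`; negative values
#' indicate weight loss.
#'
#' @param weight_day0,weight_day1 Weights (g) on the day of stress and the
#'   day after; vectorized. `weight_day0` must be positive.
#' @return Percent change.
#' @export
#' @examples
#' percent_weight_change(400, 380)  # -5
percent_weight_change <- function(weight_day0, weight_day1) {
  if (any(weight_day0 <= 0, na.rm = TRUE)) {
    abort("weight_day0 must be positive")
  }
  100 * (weight_day1 - weight_day0) / weight_day0
}

#' Pearson correlation with a two-sided t test
#'
#' Sample Pearson correlation and its two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom. Incomplete pairs are dropped
#' pairwise with a warning (mirroring cohorts with missing weight records).
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs).
#' @return A tibble (`r`, `p_value`, `n`, `df`).
#' @export
#' @examples
#' pearson_correlation(1:4, c(1, 3, 2, 4))  # r = 0.8
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y) & is.finite(x) & is.finite(y)
  if (any(!ok)) {
    warn(sprintf("dropping %d incomplete pair(s) from the correlation", sum(!ok)))
    x <- x[ok]; y <- y[ok]
  }
  if (length(x) < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in x or y")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), df = unname(ct$parameter))
}

#' Percent of variance explained by a correlation
#'
#' `100 * r^2`, rounded to the configured number of digits (default: the
#' nearest integer, the convention for reporting shared variance).
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @param digits Rounding digits.
#' @return Percent variance explained.
#' @export
#' @examples
#' variance_explained(0.5512)  # 30
variance_explained <- function(r, digits = 0) {
  if (any(abs(r) > 1)) abort("|r| must not exceed 1")
  round(100 * r^2, digits)
}

#' Correlate physiology-derived measures with composite scores
#'
#' Joins a physiology table onto a score table by `animal_id`, derives
#' percent weight change, and reports Pearson correlations of the requested
#' physiology variables against a score column.
#'
#' @param scores Score tibble with `animal_id` and `score_col`.
#' @param physiology Tibble with `animal_id`, `weight_day0`, `weight_day1`,
#'   `cort_30min`, `cort_3h`.
#' @param vars Physiology variables to correlate; any of `weight_change`,
#'   `cort_30min`, `cort_3h`.
#' @param score_col Score column name.
#' @return A tibble with one row per variable (`variable`, `r`, `p_value`,
#'   `n`, `df`).
#' @export
correlate_physiology <- function(scores, physiology,
                                 vars = c("weight_change", "cort_30min", "cort_3h"),
                                 score_col = "total") {
  scores <- tibble::as_tibble(scores)
  physiology <- tibble::as_tibble(physiology)
  assert_columns(scores, c("animal_id", score_col), "score table")
  assert_columns(physiology, "animal_id", "physiology table")
  dat <- dplyr::inner_join(scores, physiology, by = "animal_id")
  if ("weight_change" %in% vars) {
    dat$weight_change <- percent_weight_change(dat$weight_day0, dat$weight_day1)
  }
  purrr::map_dfr(vars, function(v) {
    res <- pearson_correlation(dat[[v]], dat[[score_col]])
    dplyr::bind_cols(tibble::tibble(variable = v), res)
  })
}
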