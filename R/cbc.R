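#' Derive per-metric cutoff thresholds from the control distribution
#'
#' For each registry metric, the behavioral cutoff is the 20th percentile of
#' the control values when low values indicate the affected state
#' (`LOW_IS_AFFECTED`), and the 80th percentile when high values do
#' (`HIGH_IS_AFFECTED`) — i.e. roughly the most extreme fifth of controls
#' falls beyond its own cutoff on every measure. Thresholds are always
#' derived from control animals only.
#'
#' @param measurements Data frame with `animal_id`, `group`, `metric_name`,
#'   `value` (long format, one row per animal x metric).
#' @param registry Metric registry; see [default_metric_registry()].
#' @param percentile_method `"linear"` (interpolation between order
#'   statistics, the default) or `"nearest_rank"`.
#' @return A tibble (`metric_name`, `assay`, `domain`, `direction`,
#'   `percentile_used`, `cutoff_value`, `n_controls`).
#' @export
#' @examples
#' m <- data.frame(animal_id = sprintf("a%02d", 1:10), group = "control",
#'                 assay = "LD", metric_name = "ld_time_light_side",
#'                 value = 1:10)
#' reg <- data.frame(assay = "LD", metric_name = "ld_time_light_side",
#'                   domain = "avoidance", direction = "LOW_IS_AFFECTED",
#'                   control_mean = 5, control_sd = 3)
#' derive_thresholds(m, reg)$cutoff_value  # 2.8
derive_thresholds <- function(measurements, registry,
                              percentile_method = c("linear", "nearest_rank")) {
  percentile_method <- match.arg(percentile_method)
  measurements <- tibble::as_tibble(measurements)
  assert_columns(measurements, c("animal_id", "group", "metric_name", "value"),
                 "measurement table")
  registry <- validate_registry(registry)
  ctrl <- measurements[measurements$group == "control", ]
  purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    m <- registry[i, ]
    vals <- ctrl$value[ctrl$metric_name == m$metric_name]
    if (length(vals) < 2L) {
      abort(sprintf("metric '%s': need at least 2 control values, got %d",
                    m$metric_name, length(vals)))
    }
    if (anyNA(vals) || any(!is.finite(vals))) {
      abort(sprintf("metric '%s': control values contain NA or non-finite entries",
                    m$metric_name))
    }
    p <- if (m$direction == "LOW_IS_AFFECTED") 0.2 else 0.8
    tibble::tibble(metric_name = m$metric_name, assay = m$assay,
                   domain = m$domain, direction = m$direction,
                   percentile_used = 100 * p,
                   cutoff_value = percentile_value(vals, p, percentile_method),
                   n_controls = length(vals))
  })
}

#' Binary affected score for one measurement
#'
#' An animal is "affected" on a measure when its value falls strictly beyond
#' the cutoff in the affected direction: below the 20th-percentile cutoff
#' for `LOW_IS_AFFECTED` metrics, above the 80th-percentile cutoff for
#' `HIGH_IS_AFFECTED`. Values exactly at the cutoff score 0.
#'
#' @param value Measurement value(s); vectorized.
#' @param cutoff_value Cutoff(s) from [derive_thresholds()].
#' @param direction `"LOW_IS_AFFECTED"` or `"HIGH_IS_AFFECTED"` (recycled).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' score_measure(2.0, 2.8, "LOW_IS_AFFECTED")   # 1
#' score_measure(2.8, 2.8, "LOW_IS_AFFECTED")   # 0
score_measure <- function(value, cutoff_value, direction) {
  if (!all(direction %in% c("LOW_IS_AFFECTED", "HIGH_IS_AFFECTED"))) {
    abort("direction must be LOW_IS_AFFECTED or HIGH_IS_AFFECTED")
  }
  if (anyNA(value) || any(!is.finite(value))) abort("values must be finite")
  n <- max(length(value), length(cutoff_value), length(direction))
  value <- rep_len(value, n)
  cutoff_value <- rep_len(cutoff_value, n)
  direction <- rep_len(direction, n)
  as.integer(ifelse(direction == "LOW_IS_AFFECTED",
                    value < cutoff_value, value > cutoff_value))
}

#' Composite Cutoff-Behavioral-Criteria scores
#'
#' Scores every animal on every registry metric against the control-derived
#' thresholds and sums the binary flags into an avoidance sub-score (0 to
#' the number of avoidance metrics, 20 by default), a startle sub-score, and
#' their total. High scores represent consistent anxiety-like behavior
#' across tests.
#'
#' @inheritParams derive_thresholds
#' @param thresholds Output of [derive_thresholds()]; derived on the fly
#'   when `NULL`.
#' @return A tibble (`animal_id`, `group`, `avoidance_subscore`,
#'   `startle_subscore`, `total`).
#' @export
composite_scores <- function(measurements, registry, thresholds = NULL,
                             percentile_method = c("linear", "nearest_rank")) {
  measurements <- tibble::as_tibble(measurements)
  registry <- validate_registry(registry)
  if (is.null(thresholds)) {
    thresholds <- derive_thresholds(measurements, registry, percentile_method)
  }
  dat <- dplyr::inner_join(
    measurements[measurements$metric_name %in% registry$metric_name, ],
    thresholds[, c("metric_name", "domain", "direction", "cutoff_value")],
    by = "metric_name")
  # every animal must carry every registry metric
  counts <- table(dat$animal_id)
  incomplete <- names(counts)[counts < nrow(registry)]
  if (length(incomplete)) {
    missing <- vapply(incomplete, function(id) {
      paste(setdiff(registry$metric_name,
                    dat$metric_name[dat$animal_id == id]), collapse = ", ")
    }, character(1))
    abort(paste0("missing metric(s) for animal(s): ",
                 paste(sprintf("%s [%s]", incomplete, missing), collapse = "; ")))
  }
  dat$affected <- score_measure(dat$value, dat$cutoff_value, dat$direction)
  dat |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::summarise(
      avoidance_subscore = sum(.data$affected[.data$domain == "avoidance"]),
      startle_subscore = sum(.data$affected[.data$domain == "startle"]),
      .groups = "drop") |>
    dplyr::mutate(total = .data$avoidance_subscore + .data$startle_subscore) |>
    dplyr::arrange(.data$animal_id)
}

#' Classify stress phenotypes from composite scores
#'
#' Stress-exposed animals whose composite score exceeds the maximum observed
#' control score fall outside the control range and are labeled
#' `vulnerable`; those within the control range (including ties with the
#' control maximum) are `resilient`. Control animals always keep the
#' `control` label.
#'
#' @param scores Tibble from [composite_scores()] (needs `animal_id`,
#'   `group`, and the score column).
#' @param score_col Which score column drives classification (default
#'   `"total"`).
#' @return `scores` with an added `label` column
#'   (`control`/`resilient`/`vulnerable`).
#' @export
classify_phenotype <- function(scores, score_col = "total") {
  scores <- tibble::as_tibble(scores)
  assert_columns(scores, c("animal_id", "group", score_col), "score table")
  ctrl <- scores[[score_col]][scores$group == "control"]
  if (length(ctrl) == 0L) abort("no control animals: cannot define the control range")
  cmax <- max(ctrl)
  scores$label <- ifelse(scores$group == "control", "control",
                         ifelse(scores[[score_col]] > cmax,
                                "vulnerable", "resilient"))
  scores
}

#' Select animals for sequencing
#'
#' Picks the `k_low` lowest- and `k_high` highest-scoring stress-exposed
#' animals plus `k_control` control animals spanning the control score
#' range (evenly spaced by score rank). Ties are broken deterministically by
#' animal id (lexicographic).
#'
#' @param scores Classified score tibble (from [classify_phenotype()] or
#'   [composite_scores()]).
#' @param k_low,k_high Numbers of low/high scoring stress animals.
#' @param k_control Number of control animals.
#' @param score_col Score column used for ranking.
#' @return A tibble (`animal_id`, `group`, score column, `stratum` in
#'   `control`/`stress_low`/`stress_high`).
#' @export
select_for_sequencing <- function(scores, k_low = 3, k_high = 3,
                                  k_control = 6, score_col = "total") {
  scores <- tibble::as_tibble(scores)
  assert_columns(scores, c("animal_id", "group", score_col), "score table")
  stress <- scores[scores$group == "stress", ]
  ctrl <- scores[scores$group == "control", ]
  if (nrow(stress) < k_low + k_high) {
    abort(sprintf("need %d stress animals, have %d", k_low + k_high, nrow(stress)))
  }
  if (nrow(ctrl) < k_control) {
    abort(sprintf("need %d control animals, have %d", k_control, nrow(ctrl)))
  }
  stress <- stress[order(stress[[score_col]], stress$animal_id), ]
  low <- head(stress, k_low)
  stress_desc <- stress[order(-stress[[score_col]], stress$animal_id), ]
  high <- head(stress_desc, k_high)
  if (k_low > 0 && k_high > 0 &&
      length(intersect(low$animal_id, high$animal_id))) {
    abort("low and high strata overlap; too few stress animals for disjoint strata")
  }
  ctrl <- ctrl[order(ctrl[[score_col]], ctrl$animal_id), ]
  sel_ctrl <- if (k_control > 0) {
    idx <- round(seq(1, nrow(ctrl), length.out = k_control))
    # rounding can collide for small n; walk duplicates forward
    for (i in seq_along(idx)[-1]) {
      if (idx[i] <= idx[i - 1]) idx[i] <- idx[i - 1] + 1L
    }
    ctrl[idx, ]
  } else ctrl[0, ]
  out <- dplyr::bind_rows(
    dplyr::mutate(sel_ctrl, stratum = "control"),
    dplyr::mutate(low, stratum = "stress_low"),
    dplyr::mutate(high, stratum = "stress_high"))
  out[, c("animal_id", "group", score_col, "stratum")]
}

#' Mean and standard error of a score group
#'
#' @param values Numeric vector (at least one value).
#' @return A tibble (`mean`, `sem`, `n`); the SEM is the sample SD (n-1
#'   denominator) over `sqrt(n)`, and 0 for a single value.
#' @export
#' @examples
#' group_summary(c(13, 14, 15))  # mean 14, sem 0.58
group_summary <- function(values) {
  if (length(values) == 0L) abort("values must not be empty")
  n <- length(values)
  tibble::tibble(mean = mean(values),
                 sem = if (n == 1L) 0 else sd(values) / sqrt(n),
                 n = n)
}
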