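#' Default behavioral metric registry
#'
#' The registry enumerates every measure of the two-day behavioral battery
#' together with its "affected" direction and the control-population
#' distribution used by the synthetic cohort generator. The avoidance battery
#' contributes 20 metrics — five per open field test (bright and dim), three
#' per elevated plus maze (bright and dim), and four for the light-dark box —
#' which is what caps the avoidance composite sub-score at 20. Two acoustic
#' startle metrics (mean startle and sensitization) form a separate startle
#' domain scored on top of, never inside, the 0-20 avoidance scale.
#'
#' Directions encode the anxiety reading of each measure: latencies to enter
#' an anxiogenic zone and time spent in protected zones rise with anxiety
#' (`HIGH_IS_AFFECTED`, scored against the 80th control percentile), while
#' time/frequency in anxiogenic zones and locomotion fall with anxiety
#' (`LOW_IS_AFFECTED`, scored against the 20th control percentile).
#'
#' Control means and SDs are generator defaults in natural units (seconds,
#' counts, centimeters); they are not estimates from any real cohort and
#' should be replaced when emulating a specific dataset. Startle rows carry
#' `NA` because their control distribution emerges from simulated activity
#' traces rather than from the registry.
#'
#' @param distribution Sampling family for control values, `"gaussian"`
#'   (default) or `"lognormal"` (moment-matched; useful for latencies).
#' @return A tibble with columns `assay`, `metric_name`, `domain`,
#'   `direction`, `control_mean`, `control_sd`, `distribution`.
#' @export
#' @examples
#' default_metric_registry()
default_metric_registry <- function(distribution = c("gaussian", "lognormal")) {
  distribution <- match.arg(distribution)
  oft <- function(assay, lat_m, time_m) tibble::tribble(
    ~assay, ~metric_name, ~direction, ~control_mean, ~control_sd,
    assay, paste0(tolower(assay), "_latency_to_center"),  "HIGH_IS_AFFECTED", lat_m, lat_m * 0.6,
    assay, paste0(tolower(assay), "_frequency_in_center"), "LOW_IS_AFFECTED", 15,    6,
    assay, paste0(tolower(assay), "_time_in_center"),      "LOW_IS_AFFECTED", time_m, time_m * 0.4,
    assay, paste0(tolower(assay), "_total_distance"),      "LOW_IS_AFFECTED", 3500,  700,
    assay, paste0(tolower(assay), "_center_distance"),     "LOW_IS_AFFECTED", 320,   130
  )
  epm <- function(assay, open_m) tibble::tribble(
    ~assay, ~metric_name, ~direction, ~control_mean, ~control_sd,
    assay, paste0(tolower(assay), "_latency_to_open_arms"), "HIGH_IS_AFFECTED", 60,  40,
    assay, paste0(tolower(assay), "_time_in_open_arms"),    "LOW_IS_AFFECTED",  open_m, open_m * 0.45,
    assay, paste0(tolower(assay), "_time_in_closed_arms"),  "HIGH_IS_AFFECTED", 420, 70
  )
  ld <- tibble::tribble(
    ~assay, ~metric_name, ~direction, ~control_mean, ~control_sd,
    "LD", "ld_total_distance",       "LOW_IS_AFFECTED",  2000, 500,
    "LD", "ld_latency_to_light_side", "HIGH_IS_AFFECTED", 45,  30,
    "LD", "ld_frequency_light_side", "LOW_IS_AFFECTED",  10,   4,
    "LD", "ld_time_light_side",      "LOW_IS_AFFECTED",  120, 50
  )
  asr <- tibble::tribble(
    ~assay, ~metric_name, ~direction, ~control_mean, ~control_sd,
    "ASR", "asr_mean_startle",       "HIGH_IS_AFFECTED", NA_real_, NA_real_,
    "ASR", "asr_sensitization_pct",  "HIGH_IS_AFFECTED", NA_real_, NA_real_
  )
  reg <- dplyr::bind_rows(
    oft("OFT_LIGHT", lat_m = 40, time_m = 55),
    oft("OFT_DIM",   lat_m = 25, time_m = 75),
    epm("EPM_LIGHT", open_m = 80),
    epm("EPM_DIM",   open_m = 120),
    ld, asr
  )
  reg$domain <- ifelse(reg$assay == "ASR", "startle", "avoidance")
  reg$distribution <- distribution
  validate_registry(reg)
}

validate_registry <- function(registry) {
  assert_columns(registry, c("assay", "metric_name", "direction",
                             "control_mean", "control_sd"), "metric registry")
  if (anyDuplicated(registry$metric_name)) {
    abort("metric names must be unique within the registry")
  }
  if (!all(registry$direction %in% c("LOW_IS_AFFECTED", "HIGH_IS_AFFECTED"))) {
    abort("direction must be LOW_IS_AFFECTED or HIGH_IS_AFFECTED")
  }
  if (is.null(registry$domain)) {
    registry$domain <- ifelse(registry$assay == "ASR", "startle", "avoidance")
  }
  non_asr <- registry[registry$domain == "avoidance", ]
  if (any(!is.na(non_asr$control_sd) & non_asr$control_sd <= 0)) {
    abort("control_sd must be positive for every avoidance metric")
  }
  tibble::as_tibble(registry)
}
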