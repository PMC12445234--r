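#' Configure a synthetic stress cohort
#'
#' Bundles every knob of the synthetic cohort generator. Defaults reproduce
#' the analyzed study design: 19 control and 20 stress-exposed animals, a
#' 30% vulnerable latent fraction among the stressed animals, a 3
#' control-SD shift of every avoidance metric in vulnerable animals, and a
#' target correlation of 0.55 between end-of-stress corticosterone and
#' latent anxiety.
#'
#' @param n_control,n_stress Group sizes (each at least 2).
#' @param vulnerable_fraction Probability that a stress-exposed animal
#'   belongs to the vulnerable latent class.
#' @param registry Metric registry; see [default_metric_registry()].
#' @param anxiety_shift_sd Shift (in control-SD units) applied to every
#'   avoidance metric of vulnerable-latent animals, toward the affected
#'   direction. Must be non-negative.
#' @param metric_loading Correlation loading of each avoidance metric on the
#'   animal-level shared anxiety factor (0-1). Controls how consistent one
#'   animal's behavior is across assays.
#' @param cort_behavior_r Target Pearson correlation between 3-h
#'   corticosterone and latent anxiety.
#' @param weight_loss_params Named list with `control_mean`, `control_sd`,
#'   `stress_mean`, `stress_sd`: percent body-weight change from the day of
#'   stress to the next day (negative = loss).
#' @param include_traces Generate per-animal startle activity traces (and
#'   derive startle metrics from them). When `FALSE`, startle metrics are
#'   derived from the same per-pulse response heights without rendering
#'   traces.
#' @param seed Master seed; split into per-stage substreams.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_control
cohort_config <- function(n_control = 19,
                          n_stress = 20,
                          vulnerable_fraction = 0.3,
                          registry = default_metric_registry(),
                          anxiety_shift_sd = 3,
                          metric_loading = 0.3,
                          cort_behavior_r = 0.55,
                          weight_loss_params = list(control_mean = 0.5,
                                                    control_sd = 1.0,
                                                    stress_mean = -4.0,
                                                    stress_sd = 1.5),
                          include_traces = TRUE,
                          seed = 1) {
  assert_scalar_number(n_control, "n_control")
  assert_scalar_number(n_stress, "n_stress")
  if (n_control < 2 || n_stress < 2) {
    abort("n_control and n_stress must each be at least 2")
  }
  assert_scalar_number(vulnerable_fraction, "vulnerable_fraction")
  if (vulnerable_fraction < 0 || vulnerable_fraction > 1) {
    abort("vulnerable_fraction must lie in [0, 1]")
  }
  assert_scalar_number(anxiety_shift_sd, "anxiety_shift_sd")
  if (anxiety_shift_sd < 0) abort("anxiety_shift_sd must be non-negative")
  assert_scalar_number(metric_loading, "metric_loading")
  if (metric_loading < 0 || metric_loading >= 1) {
    abort("metric_loading must lie in [0, 1)")
  }
  assert_scalar_number(cort_behavior_r, "cort_behavior_r")
  if (abs(cort_behavior_r) > 1) abort("cort_behavior_r must lie in [-1, 1]")
  registry <- validate_registry(registry)
  needed <- c("control_mean", "control_sd", "stress_mean", "stress_sd")
  if (!all(needed %in% names(weight_loss_params))) {
    abort("weight_loss_params needs control_mean, control_sd, stress_mean, stress_sd")
  }
  assert_scalar_number(seed, "seed")
  structure(list(n_control = as.integer(n_control),
                 n_stress = as.integer(n_stress),
                 vulnerable_fraction = vulnerable_fraction,
                 registry = registry,
                 anxiety_shift_sd = anxiety_shift_sd,
                 metric_loading = metric_loading,
                 cort_behavior_r = cort_behavior_r,
                 weight_loss_params = weight_loss_params,
                 include_traces = isTRUE(include_traces),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  animals: %d control + %d stress (vulnerable fraction %.2f)\n",
              x$n_control, x$n_stress, x$vulnerable_fraction))
  cat(sprintf("  anxiety shift: %.2f control SD; metric loading %.2f\n",
              x$anxiety_shift_sd, x$metric_loading))
  cat(sprintf("  cort-behavior target r: %.2f; seed %d\n",
              x$cort_behavior_r, x$seed))
  cat(sprintf("  registry: %d metrics (%d avoidance, %d startle)\n",
              nrow(x$registry), sum(x$registry$domain == "avoidance"),
              sum(x$registry$domain == "startle")))
  invisible(x)
}

#' Write or read a cohort configuration as YAML
#'
#' The registry is embedded as a list of records so a round trip preserves
#' the full configuration.
#'
#' @param config A [cohort_config()] object.
#' @param path File path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$registry <- lapply(seq_len(nrow(config$registry)),
                       function(i) as.list(config$registry[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  reg <- dplyr::bind_rows(lapply(x$registry, tibble::as_tibble))
  cohort_config(n_control = x$n_control, n_stress = x$n_stress,
                vulnerable_fraction = x$vulnerable_fraction,
                registry = reg,
                anxiety_shift_sd = x$anxiety_shift_sd,
                metric_loading = x$metric_loading,
                cort_behavior_r = x$cort_behavior_r,
                weight_loss_params = x$weight_loss_params,
                include_traces = x$include_traces,
                seed = x$seed)
}
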