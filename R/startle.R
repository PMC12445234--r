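#' Startle amplitude of one stimulus
#'
#' Amplitude is the maximum activity in the response window following pulse
#' onset minus the baseline activity, where baseline is the mean activity
#' over the second preceding onset. The response window follows (does not
#' straddle) the pulse, since startle latency trails the stimulus; both
#' windows are configurable. Amplitudes are not floored at zero: a quiet
#' response below baseline is reported as negative.
#'
#' @param trace An `activity_trace` (see [simulate_activity_trace()]), or any
#'   data frame with `time_s`/`activity` plus `sampling_rate` and `stimuli`
#'   attributes.
#' @param stimulus_index Which stimulus of the trace's schedule to score.
#' @param response_window_s Length of the post-onset response window
#'   (seconds).
#' @param baseline_window_s Length of the pre-onset baseline window
#'   (seconds).
#' @return A single amplitude (may be negative).
#' @export
#' @examples
#' tr <- simulate_activity_trace(data.frame(time_s = 2, intensity_db = 110),
#'                               startle_gain = 8, noise_sd = 0)
#' startle_amplitude(tr, 1)  # 8
startle_amplitude <- function(trace, stimulus_index,
                              response_window_s = 0.05,
                              baseline_window_s = 1) {
  stimuli <- attr(trace, "stimuli")
  if (is.null(stimuli)) abort("`trace` carries no stimulus schedule")
  if (stimulus_index < 1 || stimulus_index > nrow(stimuli)) {
    abort(sprintf("stimulus_index %d outside schedule (1..%d)",
                  stimulus_index, nrow(stimuli)))
  }
  onset <- stimuli$time_s[stimulus_index]
  tmax <- max(trace$time_s)
  if (onset - baseline_window_s < 0 || onset + response_window_s > tmax) {
    abort("baseline or response window exceeds trace bounds")
  }
  base_idx <- trace$time_s >= onset - baseline_window_s & trace$time_s < onset
  resp_idx <- trace$time_s >= onset & trace$time_s <= onset + response_window_s
  max(trace$activity[resp_idx]) - mean(trace$activity[base_idx])
}

#' Mean startle response
#'
#' Arithmetic mean of the per-stimulus startle amplitudes from the
#' habituation phase. The phase presents 15 identical pulses, so 15 values
#' are expected; pass `allow_any_count = TRUE` to average a different count.
#'
#' @param amplitudes Numeric vector of startle amplitudes.
#' @param n_expected Expected number of stimuli.
#' @param allow_any_count Skip the count check.
#' @return The mean amplitude.
#' @export
mean_startle <- function(amplitudes, n_expected = 15, allow_any_count = FALSE) {
  if (length(amplitudes) == 0L) abort("amplitudes must not be empty")
  if (!allow_any_count && length(amplitudes) != n_expected) {
    abort(sprintf("expected %d amplitudes, got %d (set allow_any_count = TRUE to override)",
                  n_expected, length(amplitudes)))
  }
  mean(amplitudes)
}

#' Startle sensitization
#'
#' Percent change of mean startle amplitude from the first three to the last
#' three of 15 identical stimuli:
#' `100 * (mean(a[13:15]) - mean(a[1:3])) / mean(a[1:3])`.
#' Positive values indicate sensitization, negative values habituation.
#'
#' @param amplitudes Numeric vector of at least 15 startle amplitudes; triads
#'   are taken at positions 1-3 and 13-15.
#' @return Sensitization in percent.
#' @export
#' @examples
#' sensitization(c(rep(10, 12), rep(15, 3)))  # +50
sensitization <- function(amplitudes) {
  if (length(amplitudes) < 15L) {
    abort("sensitization needs at least 15 amplitudes")
  }
  first <- mean(amplitudes[1:3])
  last <- mean(amplitudes[13:15])
  if (first == 0) abort("mean amplitude of stimuli 1-3 is zero; sensitization undefined")
  100 * (last - first) / first
}

#' Startle threshold curve
#'
#' Mean startle amplitude per stimulus intensity, from the threshold phase
#' in which 70-110 dB tones are each played several times in pseudo-random
#' order.
#'
#' @param trials Data frame with columns `intensity_db` and `amplitude`.
#' @return A tibble (`intensity_db`, `mean_amplitude`, `n_trials`) sorted by
#'   intensity.
#' @export
#' @examples
#' threshold_curve(data.frame(intensity_db = 110, amplitude = 1:5))
threshold_curve <- function(trials) {
  trials <- tibble::as_tibble(trials)
  assert_columns(trials, c("intensity_db", "amplitude"), "threshold trials")
  if (nrow(trials) == 0L) abort("threshold trials must not be empty")
  trials |>
    dplyr::group_by(.data$intensity_db) |>
    dplyr::summarise(mean_amplitude = mean(.data$amplitude),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$intensity_db)
}

#' Per-animal startle summary
#'
#' Applies [startle_amplitude()] to every stimulus of each animal's
#' habituation trace and reports mean startle and sensitization.
#'
#' @param traces Named list of `activity_trace` objects (names = animal ids).
#' @inheritParams startle_amplitude
#' @return A tibble (`animal_id`, `mean_startle`, `sensitization_pct`).
#' @export
startle_summary <- function(traces, response_window_s = 0.05,
                            baseline_window_s = 1) {
  if (is.null(names(traces))) abort("`traces` must be a named list")
  purrr::map_dfr(names(traces), function(id) {
    tr <- traces[[id]]
    amps <- vapply(seq_len(nrow(attr(tr, "stimuli"))), function(j) {
      startle_amplitude(tr, j, response_window_s, baseline_window_s)
    }, numeric(1))
    tibble::tibble(animal_id = id,
                   mean_startle = mean_startle(amps, allow_any_count = TRUE),
                   sensitization_pct = sensitization(amps))
  })
}
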