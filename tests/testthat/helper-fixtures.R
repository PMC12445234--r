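# shared builders for the test suite; everything is generated in code

fixture_path <- function(name) {
  system.file("extdata", name, package = "cbcsig")
}

load_deg_fixtures <- function() {
  list(
    slsh = read_deg_table(fixture_path("table1_dg.tsv"), "DG", "SL_vs_SH"),
    csl = read_deg_table(fixture_path("table2_dg.tsv"), "DG", "C_vs_SL"),
    csh = read_deg_table(fixture_path("table3_dg.tsv"), "DG", "C_vs_SH"))
}

# one-metric registry for threshold unit tests
mini_registry <- function(direction = "LOW_IS_AFFECTED") {
  tibble::tibble(assay = "LD", metric_name = "ld_time_light_side",
                 domain = "avoidance", direction = direction,
                 control_mean = 5, control_sd = 3,
                 distribution = "gaussian")
}

mini_measurements <- function(values, group = "control",
                              metric = "ld_time_light_side") {
  tibble::tibble(animal_id = sprintf("%s%02d", substr(group, 1, 1),
                                     seq_along(values)),
                 group = group, assay = "LD", metric_name = metric,
                 value = values)
}

# a trace with a hand-placed transient; attrs claim the stimulus at `onset`
manual_trace <- function(onset = 2, transient_at = onset, baseline = 2,
                         height = 8, duration = 4, rate = 100) {
  n <- duration * rate + 1
  time_s <- (seq_len(n) - 1) / rate
  activity <- rep(baseline, n)
  j <- round(transient_at * rate) + 1
  activity[j] <- baseline + height
  out <- tibble::tibble(time_s = time_s, activity = activity)
  attr(out, "sampling_rate") <- rate
  attr(out, "stimuli") <- tibble::tibble(time_s = onset, intensity_db = 110)
  class(out) <- c("activity_trace", class(out))
  out
}

# independent percentile oracle: interpolation between order statistics,
# written from the definition (not via quantile())
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(xs)) return(xs[lo])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}
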