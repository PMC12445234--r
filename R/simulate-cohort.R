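#' Simulate a stress cohort with latent resilient/vulnerable structure
#'
#' Generates a full synthetic cohort: animal roster with latent classes and
#' latent anxiety, one measurement per registry metric per animal, startle
#' activity traces with pulse-locked transients, and per-animal physiology
#' (body weights around the stressor, corticosterone at 30 min and 3 h).
#'
#' Each animal carries a shared anxiety factor `a0 ~ N(0, 1)`. An avoidance
#' metric's standardized deviation is
#' `z = loading * a0 + sqrt(1 - loading^2) * noise + shift * vulnerable`,
#' oriented toward the metric's affected direction, so control values follow
#' exactly the registry distribution while vulnerable-latent animals are
#' displaced by `anxiety_shift_sd` control-SDs on every avoidance metric.
#' Latent anxiety is `a0` plus the shift for vulnerable animals. 3-h
#' corticosterone is constructed to correlate with latent anxiety at
#' approximately `cort_behavior_r`. Startle responsiveness is drawn
#' independently of the latent class.
#'
#' Identical configuration and seed reproduce identical cohorts.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `cohort`: a list with tibbles `animals`
#'   (`animal_id`, `group`, `latent_class`, `latent_anxiety`),
#'   `measurements` (`animal_id`, `group`, `assay`, `metric_name`, `value`),
#'   `physiology` (`animal_id`, `weight_day0`, `weight_day1`, `cort_30min`,
#'   `cort_3h`), a named list `traces` of [simulate_activity_trace()]
#'   results (or `NULL`), and the `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7, include_traces = FALSE))
#' nrow(coh$animals)
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created with cohort_config()")
  }
  reg <- config$registry
  nc <- config$n_control
  ns <- config$n_stress
  n <- nc + ns
  ids <- c(sprintf("C%02d", seq_len(nc)), sprintf("S%02d", seq_len(ns)))
  group <- c(rep("control", nc), rep("stress", ns))

  set.seed(substream_seed(config$seed, "classes"))
  vulnerable <- c(rep(FALSE, nc),
                  rbinom(ns, 1L, config$vulnerable_fraction) == 1L)
  latent_class <- ifelse(group == "control", "none",
                         ifelse(vulnerable, "vulnerable_latent", "resilient_latent"))

  set.seed(substream_seed(config$seed, "latent"))
  a0 <- rnorm(n)
  shift <- config$anxiety_shift_sd * as.numeric(vulnerable)
  latent_anxiety <- a0 + shift

  animals <- tibble::tibble(animal_id = ids, group = group,
                            latent_class = latent_class,
                            latent_anxiety = latent_anxiety)

  # avoidance metrics
  set.seed(substream_seed(config$seed, "metrics"))
  avo <- reg[reg$domain == "avoidance", ]
  rho <- config$metric_loading
  meas <- purrr::map_dfr(seq_len(nrow(avo)), function(i) {
    m <- avo[i, ]
    z <- rho * a0 + sqrt(1 - rho^2) * rnorm(n) + shift
    sign <- if (m$direction == "HIGH_IS_AFFECTED") 1 else -1
    if (identical(m$distribution, "lognormal")) {
      s2 <- log(1 + (m$control_sd / m$control_mean)^2)
      value <- exp(log(m$control_mean) - s2 / 2 + sqrt(s2) * sign * z)
    } else {
      value <- m$control_mean + sign * m$control_sd * z
    }
    tibble::tibble(animal_id = ids, group = group, assay = m$assay,
                   metric_name = m$metric_name, value = value)
  })

  # startle: per-animal gain and habituation trajectory over 15 pulses
  set.seed(substream_seed(config$seed, "startle"))
  n_pulses <- 15L
  gain0 <- exp(rnorm(n, log(8), 0.4))
  habit <- runif(n, 0.90, 1.00)
  jitter <- matrix(exp(rnorm(n * n_pulses, 0, 0.10)), n, n_pulses)
  heights <- gain0 * outer(habit, seq_len(n_pulses) - 1, "^") * jitter
  onsets <- 5 + cbind(0, t(apply(matrix(runif(n * (n_pulses - 1), 15, 30),
                                        n, n_pulses - 1), 1, cumsum)))
  trace_seeds <- sample.int(2147483587L, n)

  traces <- NULL
  amplitudes <- matrix(NA_real_, n, n_pulses)
  if (config$include_traces) {
    traces <- lapply(seq_len(n), function(i) {
      sched <- tibble::tibble(time_s = onsets[i, ], intensity_db = 110)
      simulate_activity_trace(sched, startle_gain = heights[i, ],
                              noise_sd = 0.2, seed = trace_seeds[i])
    })
    names(traces) <- ids
    for (i in seq_len(n)) {
      amplitudes[i, ] <- vapply(seq_len(n_pulses), function(j) {
        startle_amplitude(traces[[i]], j)
      }, numeric(1))
    }
  } else {
    amplitudes <- heights
  }
  asr <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(animal_id = ids[i], group = group[i], assay = "ASR",
                   metric_name = c("asr_mean_startle", "asr_sensitization_pct"),
                   value = c(mean_startle(amplitudes[i, ]),
                             sensitization(amplitudes[i, ])))
  })
  keep_asr <- reg$metric_name[reg$domain == "startle"]
  measurements <- dplyr::bind_rows(meas, asr[asr$metric_name %in% keep_asr, ])

  # physiology
  set.seed(substream_seed(config$seed, "physiology"))
  wlp <- config$weight_loss_params
  w0 <- rnorm(n, 400, 25)
  pct <- ifelse(group == "control",
                rnorm(n, wlp$control_mean, wlp$control_sd),
                rnorm(n, wlp$stress_mean, wlp$stress_sd))
  w1 <- w0 * (1 + pct / 100)
  cort30 <- pmax(0, ifelse(group == "control", rnorm(n, 40, 15),
                           rnorm(n, 250, 60)))
  r <- config$cort_behavior_r
  zl <- as.numeric(scale(latent_anxiety))
  cort3h <- pmax(0, 180 + 70 * (r * zl + sqrt(1 - r^2) * rnorm(n)))
  physiology <- tibble::tibble(animal_id = ids, weight_day0 = w0,
                               weight_day1 = w1, cort_30min = cort30,
                               cort_3h = cort3h)

  structure(list(animals = animals, measurements = measurements,
                 physiology = physiology, traces = traces, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>\n")
  cat(sprintf("  %d animals (%d control, %d stress; %d vulnerable-latent)\n",
              nrow(x$animals), sum(x$animals$group == "control"),
              sum(x$animals$group == "stress"),
              sum(x$animals$latent_class == "vulnerable_latent")))
  cat(sprintf("  %d measurements across %d metrics; traces: %s\n",
              nrow(x$measurements),
              length(unique(x$measurements$metric_name)),
              if (is.null(x$traces)) "no" else "yes"))
  invisible(x)
}

#' Simulate one startle activity trace
#'
#' Builds a uniformly sampled activity signal (a percent-pixel-change
#' surrogate): Gaussian baseline noise around `baseline` plus, at each
#' stimulus onset, an exponentially decaying transient whose peak height is
#' `startle_gain * intensity_db / 110`. With zero noise the peak equals the
#' injected height exactly, so downstream [startle_amplitude()] recovers it.
#'
#' @param stimuli Data frame with columns `time_s` (strictly increasing) and
#'   `intensity_db`.
#' @param startle_gain Per-stimulus gain (recycled). Zero gives a flat trace.
#' @param duration_s Trace duration; defaults to one second past the last
#'   stimulus.
#' @param sampling_rate Samples per second.
#' @param baseline Baseline activity level.
#' @param noise_sd SD of baseline noise.
#' @param decay_s Time constant of the transient decay.
#' @param seed Optional seed for the noise stream.
#' @return An `activity_trace`: a tibble (`time_s`, `activity`) with
#'   attributes `sampling_rate` and `stimuli`.
#' @export
#' @examples
#' tr <- simulate_activity_trace(data.frame(time_s = 2, intensity_db = 110),
#'                               startle_gain = 5, noise_sd = 0)
#' startle_amplitude(tr, 1)
simulate_activity_trace <- function(stimuli, startle_gain,
                                    duration_s = NULL, sampling_rate = 100,
                                    baseline = 2, noise_sd = 0,
                                    decay_s = 0.02, seed = NULL) {
  stimuli <- tibble::as_tibble(stimuli)
  assert_columns(stimuli, c("time_s", "intensity_db"), "stimulus schedule")
  if (nrow(stimuli) == 0L) abort("stimulus schedule must not be empty")
  if (is.unsorted(stimuli$time_s, strictly = TRUE)) {
    abort("stimulus times must be strictly increasing")
  }
  if (is.null(duration_s)) duration_s <- max(stimuli$time_s) + 1
  if (any(stimuli$time_s < 0) || any(stimuli$time_s > duration_s)) {
    abort("stimulus times must lie within the trace duration")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_s * sampling_rate) + 1L
  time_s <- (seq_len(n) - 1L) / sampling_rate
  activity <- rep(baseline, n) + (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
  gains <- rep_len(startle_gain, nrow(stimuli))
  k <- max(1L, round(2 * decay_s * sampling_rate))
  for (i in seq_len(nrow(stimuli))) {
    h <- gains[i] * stimuli$intensity_db[i] / 110
    if (h == 0) next
    j0 <- round(stimuli$time_s[i] * sampling_rate) + 1L
    jj <- j0:min(n, j0 + k)
    activity[jj] <- activity[jj] + h * exp(-(jj - j0) / (decay_s * sampling_rate))
  }
  activity <- pmax(activity, 0)
  out <- tibble::tibble(time_s = time_s, activity = activity)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "stimuli") <- stimuli
  class(out) <- c("activity_trace", class(out))
  out
}

#' Specify a count-simulation design with planted fold changes
#'
#' @param n_genes Number of genes.
#' @param gene_lengths Positive gene lengths in bp; defaults to a seeded
#'   log-uniform draw over 500-5000 bp.
#' @param baseline_mean Per-gene baseline expected counts; defaults to a
#'   seeded log-uniform draw over 20-500. An all-zero baseline is rejected.
#' @param dispersion Common negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2). Zero gives Poisson counts.
#' @param planted Data frame with columns `gene_id`, `affected_group`
#'   (one of `stress_low`, `stress_high`, `stress`), `log2_fold_change`;
#'   or `NULL` for a null design.
#' @param seed Seed for the default length/baseline draws.
#' @return An object of class `de_plant_spec`.
#' @export
de_plant_spec <- function(n_genes, gene_lengths = NULL, baseline_mean = NULL,
                          dispersion = 0.05, planted = NULL, seed = 1000) {
  assert_scalar_number(n_genes, "n_genes")
  assert_scalar_number(dispersion, "dispersion")
  if (dispersion < 0) abort("dispersion must be non-negative")
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  set.seed(substream_seed(seed, "plant_defaults"))
  if (is.null(gene_lengths)) {
    gene_lengths <- round(exp(runif(n_genes, log(500), log(5000))))
  }
  if (is.null(baseline_mean)) {
    baseline_mean <- exp(runif(n_genes, log(20), log(500)))
  }
  if (length(gene_lengths) != n_genes || any(gene_lengths <= 0)) {
    abort("gene_lengths must be positive and of length n_genes")
  }
  if (length(baseline_mean) != n_genes || any(baseline_mean < 0)) {
    abort("baseline_mean must be non-negative and of length n_genes")
  }
  if (all(baseline_mean == 0)) abort("all-zero baseline_mean is not a valid design")
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    assert_columns(planted, c("gene_id", "affected_group", "log2_fold_change"),
                   "planted gene table")
    bad <- setdiff(planted$gene_id, gene_ids)
    if (length(bad)) {
      abort(sprintf("planted gene id(s) not in the design: %s",
                    paste(bad, collapse = ", ")))
    }
    if (!all(planted$affected_group %in% c("stress_low", "stress_high", "stress"))) {
      abort("affected_group must be stress_low, stress_high or stress")
    }
  }
  structure(list(n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 gene_lengths = as.numeric(gene_lengths),
                 baseline_mean = as.numeric(baseline_mean),
                 dispersion = dispersion, planted = planted),
            class = "de_plant_spec")
}

#' Simulate a gene-by-sample count matrix with planted differences
#'
#' Draws negative-binomial counts at the spec's baseline means and common
#' dispersion, multiplies planted genes by `2^log2_fold_change` in their
#' affected group(s), and varies library sizes by +/-20%.
#'
#' @param groups Character vector of per-sample phenotype labels drawn from
#'   `control`, `stress_low`, `stress_high` (optionally named by sample id).
#' @param spec A [de_plant_spec()].
#' @param seed Seed for the count draw.
#' @return A list of class `count_sim`: `counts` (integer matrix, genes x
#'   samples), `gene_lengths`, and a `samples` tibble (`sample_id`, `group`).
#' @export
#' @examples
#' sp <- de_plant_spec(50, dispersion = 0.05)
#' cs <- simulate_counts(rep(c("control", "stress_high"), each = 3), sp, seed = 1)
#' dim(cs$counts)
simulate_counts <- function(groups, spec, seed = 1) {
  if (!inherits(spec, "de_plant_spec")) {
    abort("`spec` must be created with de_plant_spec()")
  }
  groups <- as.character(groups)
  if (!all(groups %in% c("control", "stress_low", "stress_high"))) {
    abort("groups must be control, stress_low or stress_high")
  }
  ns <- length(groups)
  sample_ids <- names(groups) %||% sprintf("%s_%d", groups,
                                           stats::ave(seq_len(ns), groups,
                                                      FUN = seq_along))
  if (!is.null(spec$planted)) {
    for (ag in unique(spec$planted$affected_group)) {
      hit <- if (ag == "stress") groups %in% c("stress_low", "stress_high")
             else groups == ag
      if (!any(hit)) {
        abort(sprintf("planted affected_group '%s' has no samples in the cohort", ag))
      }
    }
  }
  set.seed(substream_seed(seed, "counts"))
  lib <- exp(runif(ns, log(0.8), log(1.2)))
  mu <- outer(spec$baseline_mean, lib)
  if (!is.null(spec$planted)) {
    for (i in seq_len(nrow(spec$planted))) {
      p <- spec$planted[i, ]
      g <- match(p$gene_id, spec$gene_ids)
      hit <- if (p$affected_group == "stress") {
        groups %in% c("stress_low", "stress_high")
      } else groups == p$affected_group
      mu[g, hit] <- mu[g, hit] * 2^p$log2_fold_change
    }
  }
  counts <- if (spec$dispersion == 0) {
    matrix(stats::rpois(length(mu), mu), nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion), nrow(mu))
  }
  dimnames(counts) <- list(spec$gene_ids, sample_ids)
  structure(list(counts = counts, gene_lengths = spec$gene_lengths,
                 samples = tibble::tibble(sample_id = sample_ids,
                                          group = groups)),
            class = "count_sim")
}
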