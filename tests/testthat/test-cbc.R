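test_that("thresholds sit at the 20th/80th control percentile", {
  low <- derive_thresholds(mini_measurements(1:10), mini_registry("LOW_IS_AFFECTED"))
  expect_equal(low$cutoff_value, oracle_percentile(1:10, 0.2))
  expect_equal(low$cutoff_value, 2.8)
  expect_equal(low$percentile_used, 20)
  high <- derive_thresholds(mini_measurements(1:10), mini_registry("HIGH_IS_AFFECTED"))
  expect_equal(high$cutoff_value, oracle_percentile(1:10, 0.8))
  expect_equal(high$cutoff_value, 8.2)
  expect_equal(high$percentile_used, 80)
  # nearest-rank alternative: ceiling(n*p)-th order statistic
  nr <- derive_thresholds(mini_measurements(1:10), mini_registry("LOW_IS_AFFECTED"),
                          percentile_method = "nearest_rank")
  expect_equal(nr$cutoff_value, 2)
  expect_equal(low$n_controls, 10)
})

test_that("threshold derivation rejects degenerate control sets", {
  expect_error(derive_thresholds(mini_measurements(5), mini_registry()),
               "at least 2")
  expect_error(derive_thresholds(mini_measurements(c(1, NA, 3)), mini_registry()),
               "NA")
  # thresholds come from control animals only
  m <- dplyr::bind_rows(mini_measurements(1:10),
                        mini_measurements(rep(100, 5), group = "stress"))
  thr <- derive_thresholds(m, mini_registry("LOW_IS_AFFECTED"))
  expect_equal(thr$cutoff_value, 2.8)
})

test_that("binary scoring uses strict inequality beyond the cutoff", {
  expect_equal(score_measure(2.0, 2.8, "LOW_IS_AFFECTED"), 1L)
  expect_equal(score_measure(2.8, 2.8, "LOW_IS_AFFECTED"), 0L)
  expect_equal(score_measure(9.0, 8.2, "HIGH_IS_AFFECTED"), 1L)
  expect_equal(score_measure(8.2, 8.2, "HIGH_IS_AFFECTED"), 0L)
  # degenerate control distribution: everyone at the cutoff scores 0
  m <- dplyr::bind_rows(mini_measurements(rep(4, 6)),
                        mini_measurements(rep(4, 3), group = "stress"))
  reg <- mini_registry("LOW_IS_AFFECTED")
  sc <- composite_scores(m, reg)
  expect_true(all(sc$total == 0))
})

test_that("composite scores sum binary flags within each domain", {
  reg <- default_metric_registry()
  avo <- reg[reg$domain == "avoidance", ]
  ctrl <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(animal_id = sprintf("C%02d", i), group = "control",
                   assay = avo$assay, metric_name = avo$metric_name,
                   value = avo$control_mean + (i - 3.5) * 0.2 * avo$control_sd)
  })
  affected_value <- function(m) {
    # far beyond any control on the affected side
    ifelse(m$direction == "HIGH_IS_AFFECTED",
           m$control_mean + 10 * m$control_sd,
           m$control_mean - 10 * m$control_sd)
  }
  all_aff <- tibble::tibble(animal_id = "S01", group = "stress",
                            assay = avo$assay, metric_name = avo$metric_name,
                            value = affected_value(avo))
  none_aff <- tibble::tibble(animal_id = "S02", group = "stress",
                             assay = avo$assay, metric_name = avo$metric_name,
                             value = avo$control_mean)
  sc <- composite_scores(dplyr::bind_rows(ctrl, all_aff, none_aff), avo)
  expect_equal(sc$avoidance_subscore[sc$animal_id == "S01"], 20L)
  expect_equal(sc$total[sc$animal_id == "S02"], 0L)
  # exactly two affected metrics
  two <- none_aff
  pick <- two$metric_name %in% c("oft_light_latency_to_center", "ld_time_light_side")
  two$value[pick] <- affected_value(avo[match(two$metric_name[pick],
                                              avo$metric_name), ])
  two$animal_id <- "S03"
  sc3 <- composite_scores(dplyr::bind_rows(ctrl, two), avo)
  expect_equal(sc3$avoidance_subscore[sc3$animal_id == "S03"], 2L)
  # missing metric is a named error
  expect_error(composite_scores(dplyr::bind_rows(ctrl, all_aff[-1, ]), avo),
               "missing metric.*S01")
})

test_that("composite total is monotone in the affected direction", {
  reg <- mini_registry("LOW_IS_AFFECTED")
  base <- dplyr::bind_rows(mini_measurements(1:10),
                           mini_measurements(5, group = "stress"))
  sc0 <- composite_scores(base, reg)$total[11]
  worse <- base
  worse$value[worse$group == "stress"] <- 1.5   # further toward affected
  sc1 <- composite_scores(worse, reg)$total[11]
  expect_gte(sc1, sc0)
})

test_that("about a fifth of a large control sample is flagged per metric", {
  set.seed(404)
  n <- 10000
  m <- tibble::tibble(animal_id = sprintf("c%05d", 1:n), group = "control",
                      assay = "LD", metric_name = "ld_time_light_side",
                      value = rnorm(n, 5, 3))
  thr <- derive_thresholds(m, mini_registry("LOW_IS_AFFECTED"))
  frac <- mean(score_measure(m$value, thr$cutoff_value, thr$direction))
  expect_lt(abs(frac - 0.20), 0.02)
})

test_that("phenotype labels hinge on the observed control range", {
  sc <- tibble::tibble(animal_id = c(sprintf("C%d", 1:7), "S1", "S2"),
                       group = c(rep("control", 7), "stress", "stress"),
                       total = c(0:6, 14, 6))
  lab <- classify_phenotype(sc)
  expect_equal(lab$label[lab$animal_id == "S1"], "vulnerable")
  # a stress animal tied with the control maximum stays resilient
  expect_equal(lab$label[lab$animal_id == "S2"], "resilient")
  expect_true(all(lab$label[lab$group == "control"] == "control"))
  # all-zero cohort: every stress animal resilient
  z <- tibble::tibble(animal_id = c("C1", "C2", "S1"), total = 0,
                      group = c("control", "control", "stress"))
  expect_equal(classify_phenotype(z)$label[3], "resilient")
  expect_error(classify_phenotype(sc[sc$group == "stress", ]), "no control")
})

test_that("sequencing selection picks extremes and spans controls", {
  sc <- tibble::tibble(
    animal_id = c(sprintf("C%02d", 1:8), sprintf("S%02d", 1:7)),
    group = c(rep("control", 8), rep("stress", 7)),
    total = c(0, 1, 2, 3, 4, 5, 6, 6, 0, 1, 2, 5, 13, 14, 15))
  sel <- select_for_sequencing(sc, k_low = 3, k_high = 3, k_control = 6)
  expect_setequal(sel$animal_id[sel$stratum == "stress_low"],
                  c("S01", "S02", "S03"))
  expect_setequal(sel$animal_id[sel$stratum == "stress_high"],
                  c("S05", "S06", "S07"))
  expect_equal(sum(sel$stratum == "control"), 6)
  # empty high stratum allowed
  sel0 <- select_for_sequencing(sc, k_low = 3, k_high = 0, k_control = 2)
  expect_equal(sum(sel0$stratum == "stress_high"), 0)
  # deterministic lexicographic tie-break at the k-th rank
  tie <- tibble::tibble(animal_id = c("C1", "C2", "Sb", "Sa", "Sc"),
                        group = c("control", "control", rep("stress", 3)),
                        total = c(1, 2, 5, 5, 9))
  sel_t <- select_for_sequencing(tie, k_low = 1, k_high = 1, k_control = 2)
  expect_equal(sel_t$animal_id[sel_t$stratum == "stress_low"], "Sa")
  expect_error(select_for_sequencing(tie, k_low = 3, k_high = 3, k_control = 1),
               "stress animals")
})

test_that("group summaries report mean and SEM", {
  gs <- group_summary(c(13, 14, 15))
  expect_equal(gs$mean, 14)
  expect_equal(round(gs$sem, 2), 0.58)
  gs2 <- group_summary(c(0, 1, 2))
  expect_equal(gs2$mean, 1)
  expect_equal(round(gs2$sem, 2), 0.58)
  single <- group_summary(7)
  expect_equal(single$mean, 7)
  expect_equal(single$sem, 0)
  expect_error(group_summary(numeric(0)), "empty")
})

test_that("latent classes are recovered on shifted cohorts", {
  res <- sapply(1:25, function(s) {
    cfg <- cohort_config(anxiety_shift_sd = 3, vulnerable_fraction = 0.3,
                         seed = 2000 + s, include_traces = FALSE)
    coh <- simulate_cohort(cfg)
    lab <- classify_phenotype(composite_scores(coh$measurements, cfg$registry))
    lab <- dplyr::inner_join(lab, coh$animals, by = c("animal_id", "group"))
    c(sum(lab$latent_class == "vulnerable_latent" & lab$label == "vulnerable"),
      sum(lab$latent_class == "vulnerable_latent"),
      sum(lab$latent_class == "resilient_latent" & lab$label == "resilient"),
      sum(lab$latent_class == "resilient_latent"),
      sum(lab$group == "control" & lab$label != "control"))
  })
  expect_gte(sum(res[1, ]) / sum(res[2, ]), 0.9)
  expect_gte(sum(res[3, ]) / sum(res[4, ]), 0.9)
  expect_equal(sum(res[5, ]), 0)  # controls are never relabeled
})
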