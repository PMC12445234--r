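test_that("published-table fixtures parse with the printed row counts", {
  fx <- load_deg_fixtures()
  expect_equal(nrow(fx$slsh), 40)
  expect_equal(nrow(fx$csl), 25)
  expect_equal(nrow(fx$csh), 5)
  # the row with an unassigned name is retained but flagged
  unk <- fx$csl[fx$csl$gene_symbol == "Unknown", ]
  expect_equal(nrow(unk), 1)
  expect_true(unk$unnamed)
  expect_equal(sum(fx$slsh$unnamed), 0)
  # empty file with header parses to an empty table
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_symbol\tgene_name\tadjusted_p", path)
  empty <- read_deg_table(path, "DG", "C_vs_SL")
  expect_equal(nrow(empty), 0)
  # missing column is a parse error naming the column
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tadjusted_p", "Abc\t0.01"), path2)
  expect_error(read_deg_table(path2, "DG", "C_vs_SL"), "gene_name")
})

test_that("gene identity keys separate symbol collisions but absorb aliases", {
  # same symbol, different genes: distinct keys
  expect_false(gene_identity_key("Rpl19", "Ribosomal Protein L19") ==
                 gene_identity_key("Rpl19", "Ribosomal protein L9-like"))
  # case differences collapse
  expect_equal(gene_identity_key("CTTN", "Cortactin"),
               gene_identity_key("CTTN", "cortactin"))
  # parenthetical aliases (even nested) are stripped
  expect_equal(
    gene_identity_key("Rnf112",
                      "Ring Finger Protein 112 (also Zinc Finger Protein 179 (ZNF179))"),
    gene_identity_key("Rnf112", "Ring Finger Protein 112"))
  expect_error(gene_identity_key("", "x"), "non-empty")
  # duplicate identity keys within one table are rejected
  dup <- data.frame(gene_symbol = c("A", "A"), gene_name = c("gene a", "Gene A"),
                    adjusted_p = c(0.01, 0.02))
  expect_error(as_deg_table(dup, "DG", "C_vs_SL"), "duplicate")
})

test_that("resilience and susceptibility signatures match the printed overlaps", {
  fx <- load_deg_fixtures()
  res <- resilience_signature(fx$slsh, fx$csl)
  expect_setequal(res$gene_symbol, c("Rnf112", "Tbx19", "UBALD1", "ATN1", "CTTN"))
  expect_equal(nrow(res), 5)
  expect_equal(attr(res, "provenance"), c("SL_vs_SH", "C_vs_SL"))
  sus <- susceptibility_signature(fx$slsh, fx$csh)
  expect_equal(sus$gene_symbol, "Cartpt")
  expect_equal(nrow(sus), 1)
  # signatures are subsets of both parents
  expect_true(all(res$identity_key %in% fx$slsh$identity_key))
  expect_true(all(res$identity_key %in% fx$csl$identity_key))
  # region mismatch is an error
  other <- as_deg_table(fx$csl, "BLA", "C_vs_SL")
  expect_error(resilience_signature(fx$slsh, other), "different regions")
})

test_that("symbol-only matching would merge the colliding ribosomal entries", {
  fx <- load_deg_fixtures()
  ident_n <- nrow(resilience_signature(fx$slsh, fx$csl))
  symbol_n <- length(intersect(fx$slsh$gene_symbol, fx$csl$gene_symbol))
  expect_equal(symbol_n, ident_n + 1)   # the Rpl19 pair
})

test_that("degenerate overlaps behave as set operations", {
  fx <- load_deg_fixtures()
  empty <- as_deg_table(fx$csl[0, c("gene_symbol", "gene_name", "adjusted_p")],
                        "DG", "C_vs_SL")
  expect_equal(nrow(resilience_signature(fx$slsh, empty)), 0)
  # identical tables intersect to the full set
  self <- resilience_signature(fx$slsh, as_deg_table(
    fx$slsh[, c("gene_symbol", "gene_name", "adjusted_p")], "DG", "C_vs_SL"))
  expect_equal(nrow(self), 40)
  # a planted shared gene is exactly recovered
  a <- as_deg_table(data.frame(gene_symbol = c("X1", "X2"),
                               gene_name = c("gene x1", "gene x2"),
                               adjusted_p = 0.01), "DG", "SL_vs_SH")
  b <- as_deg_table(data.frame(gene_symbol = c("X2", "X3"),
                               gene_name = c("gene x2", "gene x3"),
                               adjusted_p = 0.01), "DG", "C_vs_SH")
  expect_equal(susceptibility_signature(a, b)$gene_symbol, "X2")
})

test_that("outlier-driven calls are flagged by the leave-one-out rule", {
  # the dispersion-aware engine is itself robust: a null gene inflated
  # 20-fold in one sample inherits a huge dispersion and is never called
  set.seed(91)
  cm <- matrix(rnbinom(400 * 6, mu = 100, size = 20), 400, 6,
               dimnames = list(sprintf("g%03d", 1:400), sprintf("s%d", 1:6)))
  groups <- rep(c("stress_low", "stress_high"), each = 3)
  cm[1, 6] <- cm[1, 6] * 20
  full <- de_test(cm, groups)
  expect_false(full$significant[1])
  # a boundary-effect gene whose call hinges on its most extreme sample
  # loses significance once that sample is removed -> flagged
  sp <- de_plant_spec(300, dispersion = 0.05, planted = data.frame(
    gene_id = "g00001", affected_group = "stress_high",
    log2_fold_change = 1.1))
  cs <- simulate_counts(rep(c("stress_low", "stress_high"), each = 3), sp,
                        seed = 1)
  res <- de_test(cs$counts, cs$samples$group)
  expect_true(res$significant[1])
  fl <- outlier_driven_flag(cs$counts, cs$samples$group, "g00001")
  expect_true(as.logical(fl))
  expect_true(attr(fl, "removed_sample") %in% cs$samples$sample_id)
  expect_gte(attr(fl, "adj_p_after"), 0.05)
  # constant gene: not significant upstream, the filter refuses to run
  cm2 <- cm; cm2[2, ] <- 50L
  expect_error(outlier_driven_flag(cm2, groups, "g002"), "not significant")
})

test_that("cleanly planted genes survive the outlier filter", {
  sp <- de_plant_spec(300, dispersion = 0.05, planted = data.frame(
    gene_id = "g00001", affected_group = "stress_high", log2_fold_change = 2))
  flagged <- sapply(1:100, function(s) {
    cs <- simulate_counts(rep(c("stress_low", "stress_high"), each = 3), sp,
                          seed = 7000 + s)
    res <- de_test(cs$counts, cs$samples$group)
    if (!res$significant[1]) return(NA)
    as.logical(outlier_driven_flag(cs$counts, cs$samples$group, "g00001"))
  })
  expect_lte(mean(flagged, na.rm = TRUE), 0.10)
})

test_that("expression-behavior correlation reports r and a normality panel", {
  scores <- c(0, 1, 2, 4, 5, 6, 13, 14, 15, 3, 7, 2)
  self <- expression_behavior_correlation(scores, scores)
  expect_equal(self$correlation$r, 1)
  expect_equal(nrow(self$normality), 2)
  expect_false(anyNA(self$normality$p_value))
  gl <- glance(self)
  expect_true(all(c("shapiro_p", "dagostino_p") %in% names(gl)))
  expect_error(expression_behavior_correlation(1:2, 1:2), "at least 3")
  expect_error(expression_behavior_correlation(rep(1, 10), 1:10), "zero variance")
})

test_that("an unrelated gene yields uniform permutation p-values", {
  set.seed(55)
  scores <- rnorm(20)
  ps <- replicate(200, {
    expr <- rnorm(20)
    suppressWarnings(expression_behavior_correlation(expr, scores)$correlation$p_value)
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the K-squared omnibus test matches an independent reference", {
  x <- c(2.3, 1.9, 3.1, 2.8, 2.2, 3.6, 2.9, 1.5, 2.7, 3.3, 2.1, 2.5)
  res <- dagostino_test(x)
  # reference values computed with an independent implementation
  expect_equal(unname(res$statistic), 0.0743362793, tolerance = 1e-8)
  expect_equal(res$p.value, 0.9635141168, tolerance = 1e-8)
  y <- c(1.0, 1.2, 0.9, 5.0, 1.1, 0.8, 1.3, 1.05, 0.95, 1.15, 1.02, 0.98,
         1.08, 0.92, 1.25)
  res_y <- dagostino_test(y)
  expect_equal(unname(res_y$statistic), 39.4166108377, tolerance = 1e-8)
  expect_lt(res_y$p.value, 1e-6)
  expect_error(dagostino_test(1:5), "at least 8")
})
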