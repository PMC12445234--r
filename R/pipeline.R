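#' Default planted differential-expression design for pipeline demos
#'
#' 2000 genes at dispersion 0.05 with one susceptibility-like gene
#' (upregulated in stress-high animals only) and two resilience-like genes
#' (shifted in stress-low animals only), so an end-to-end run recovers a
#' one-gene susceptibility signature and a two-gene resilience signature.
#'
#' @param n_genes Number of genes.
#' @param dispersion Common NB dispersion.
#' @return A [de_plant_spec()].
#' @export
default_plant_spec <- function(n_genes = 2000, dispersion = 0.05) {
  de_plant_spec(
    n_genes, dispersion = dispersion,
    planted = tibble::tibble(
      gene_id = c("g00001", "g00002", "g00003"),
      affected_group = c("stress_high", "stress_low", "stress_low"),
      log2_fold_change = c(2, -2, 2)))
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

#' Run the full scoring-to-signatures pipeline
#'
#' Executes every stage on a synthetic cohort: simulate the cohort,
#' summarize startle behavior, derive control thresholds and composite
#' scores, classify phenotypes, select animals for sequencing, simulate
#' counts with planted fold changes, quantify TPM, screen samples by PCA,
#' run the three pairwise differential-expression contrasts
#' (control vs. stress-low, control vs. stress-high, stress-low vs.
#' stress-high), intersect them into resilience and susceptibility
#' signatures, and apply the leave-one-out outlier filter to signature
#' genes. All intermediate tables are written as TSV, signatures as JSON,
#' and a manifest (config snapshot, package version, file checksums,
#' machine-readable warnings) is emitted on every run — also on failure,
#' where the error is re-raised with the failing stage's name.
#'
#' Identical configuration and seed reproduce byte-identical outputs.
#'
#' @param config A [cohort_config()].
#' @param plant A [de_plant_spec()]; see [default_plant_spec()].
#' @param output_dir Directory for outputs (created if needed).
#' @param de_alpha Adjusted-p significance threshold for DE calls.
#' @param region Region label attached to DEG tables and signatures.
#' @param apply_outlier_filter Disregard signature genes whose calls are
#'   outlier-driven.
#' @return The run manifest (list of class `cbc_manifest`), invisibly.
#' @export
run_cbc_pipeline <- function(config = cohort_config(),
                             plant = default_plant_spec(),
                             output_dir = tempfile("cbc_run_"),
                             de_alpha = 0.05, region = "DG",
                             apply_outlier_filter = TRUE) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created with cohort_config()")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cbcsig")),
    seed = config$seed,
    config = list(n_control = config$n_control, n_stress = config$n_stress,
                  vulnerable_fraction = config$vulnerable_fraction,
                  anxiety_shift_sd = config$anxiety_shift_sd,
                  metric_loading = config$metric_loading,
                  cort_behavior_r = config$cort_behavior_r,
                  n_genes = plant$n_genes, dispersion = plant$dispersion,
                  de_alpha = de_alpha, region = region),
    stages = character(0), files = list(), warnings = list())
  finish <- function() {
    paths <- unlist(manifest$files, use.names = FALSE)
    if (length(paths)) {
      manifest$checksums <- as.list(setNames(unname(tools::md5sum(paths)),
                                             basename(paths)))
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$error <<- list(stage = name, message = conditionMessage(e))
      finish()
      abort(sprintf("pipeline failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  cohort <- stage("simulate", simulate_cohort(config))
  manifest$files$measurements <- write_table(cohort$measurements, output_dir,
                                             "measurements.tsv")
  manifest$files$physiology <- write_table(cohort$physiology, output_dir,
                                           "physiology.tsv")

  scores <- stage("score", {
    thr <- derive_thresholds(cohort$measurements, config$registry)
    manifest$files$thresholds <- write_table(thr, output_dir, "thresholds.tsv")
    composite_scores(cohort$measurements, config$registry, thr)
  })
  labeled <- stage("classify", classify_phenotype(scores))
  manifest$files$scores <- write_table(labeled, output_dir, "scores.tsv")

  selection <- stage("select", select_for_sequencing(labeled))
  manifest$files$selection <- write_table(selection, output_dir, "selection.tsv")

  sim <- stage("counts", {
    groups <- setNames(selection$stratum, selection$animal_id)
    simulate_counts(groups, plant, seed = substream_seed(config$seed, "rnaseq"))
  })
  counts_df <- tibble::as_tibble(sim$counts, rownames = "gene_id")
  counts_df <- dplyr::bind_cols(counts_df[, "gene_id"],
                                tibble::tibble(length = sim$gene_lengths),
                                counts_df[, -1])
  manifest$files$counts <- write_table(counts_df, output_dir, "counts.tsv")

  qc <- stage("quantify", {
    tpm <- counts_to_tpm(sim$counts, sim$gene_lengths)
    flagged <- pca_outlier_flag(log2p1(tpm))
    if (length(flagged)) {
      manifest$warnings$pca_flagged_samples <- flagged
    }
    list(tpm = tpm, flagged = flagged)
  })
  keep <- setdiff(colnames(sim$counts), qc$flagged)
  groups <- setNames(sim$samples$group, sim$samples$sample_id)[keep]
  counts <- sim$counts[, keep, drop = FALSE]

  degs <- stage("de", {
    contrasts <- list(C_vs_SL = c("control", "stress_low"),
                      C_vs_SH = c("control", "stress_high"),
                      SL_vs_SH = c("stress_low", "stress_high"))
    lapply(names(contrasts), function(nm) {
      lv <- contrasts[[nm]]
      sel <- groups %in% lv
      res <- de_test(counts[, sel, drop = FALSE],
                     factor(groups[sel], levels = lv),
                     alpha = de_alpha, contrast = nm)
      sig <- res[res$significant,
                 c("gene_symbol", "gene_name", "adj_p", "log2_fold_change",
                   "p_value")]
      names(sig)[names(sig) == "adj_p"] <- "adjusted_p"
      manifest$files[[paste0("deg_", nm)]] <<-
        write_table(sig, output_dir, sprintf("deg_%s.tsv", nm))
      as_deg_table(sig, region, nm)
    }) |> setNames(names(contrasts))
  })

  sigs <- stage("signatures", {
    res <- resilience_signature(degs$SL_vs_SH, degs$C_vs_SL)
    sus <- susceptibility_signature(degs$SL_vs_SH, degs$C_vs_SH)
    disregarded <- character(0)
    if (apply_outlier_filter) {
      slsh <- groups %in% c("stress_low", "stress_high")
      for (g in unique(c(res$gene_symbol, sus$gene_symbol))) {
        fl <- outlier_driven_flag(counts[, slsh, drop = FALSE], groups[slsh],
                                  g, alpha = de_alpha)
        if (isTRUE(as.logical(fl))) disregarded <- c(disregarded, g)
      }
      if (length(disregarded)) {
        manifest$warnings$outlier_driven_genes <- disregarded
      }
    }
    out <- list(
      region = region,
      resilience = list(
        genes = setdiff(res$gene_symbol, disregarded),
        provenance = c("SL_vs_SH", "C_vs_SL"),
        disregarded = intersect(res$gene_symbol, disregarded)),
      susceptibility = list(
        genes = setdiff(sus$gene_symbol, disregarded),
        provenance = c("SL_vs_SH", "C_vs_SH"),
        disregarded = intersect(sus$gene_symbol, disregarded)))
    path <- file.path(output_dir, "signatures.json")
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    manifest$files$signatures <- path
    out
  })

  manifest$signatures <- sigs
  manifest <- finish()
  class(manifest) <- "cbc_manifest"
  invisible(manifest)
}

#' @export
print.cbc_manifest <- function(x, ...) {
  cat("<cbc_manifest>\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$error)) {
    cat("  FAILED at:", x$error$stage, "\n")
  } else {
    cat("  resilience genes:",
        paste(x$signatures$resilience$genes, collapse = ", "), "\n")
    cat("  susceptibility genes:",
        paste(x$signatures$susceptibility$genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate pipeline input tables
#'
#' Schema checks for the measurement, physiology and count inputs. Never
#' raises on invalid data; every failed check is one row of the report.
#'
#' @param measurements Optional measurement table.
#' @param physiology Optional physiology table.
#' @param counts Optional count matrix or data frame.
#' @param gene_lengths Optional gene lengths for `counts`.
#' @return A tibble (`input`, `check`, `ok`, `detail`); `ok = FALSE` rows
#'   are the failures.
#' @export
validate_inputs <- function(measurements = NULL, physiology = NULL,
                            counts = NULL, gene_lengths = NULL) {
  rows <- list()
  note <- function(input, check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      input = input, check = check, ok = ok, detail = detail)
  }
  if (!is.null(measurements)) {
    need <- c("animal_id", "group", "assay", "metric_name", "value")
    missing <- setdiff(need, names(measurements))
    note("measurements", "required_columns", length(missing) == 0L,
         paste(missing, collapse = ", "))
    if (!length(missing)) {
      note("measurements", "value_numeric", is.numeric(measurements$value))
      note("measurements", "groups_valid",
           all(measurements$group %in% c("control", "stress")),
           paste(setdiff(unique(measurements$group),
                         c("control", "stress")), collapse = ", "))
      dup <- duplicated(measurements[, c("animal_id", "assay", "metric_name")])
      note("measurements", "unique_animal_assay_metric", !any(dup),
           sprintf("%d duplicate row(s)", sum(dup)))
    }
  }
  if (!is.null(physiology)) {
    need <- c("animal_id", "weight_day0", "weight_day1", "cort_30min", "cort_3h")
    missing <- setdiff(need, names(physiology))
    note("physiology", "required_columns", length(missing) == 0L,
         paste(missing, collapse = ", "))
    if (!length(missing)) {
      note("physiology", "weights_positive",
           all(physiology$weight_day0 > 0 & physiology$weight_day1 > 0,
               na.rm = TRUE))
      note("physiology", "cort_non_negative",
           all(physiology$cort_30min >= 0 & physiology$cort_3h >= 0,
               na.rm = TRUE))
    }
  }
  if (!is.null(counts)) {
    cm <- as.matrix(counts)
    note("counts", "non_negative", all(cm >= 0, na.rm = TRUE),
         sprintf("%d negative entr(ies)", sum(cm < 0, na.rm = TRUE)))
    note("counts", "no_missing", !anyNA(cm))
    if (!is.null(gene_lengths)) {
      note("counts", "lengths_match_genes", length(gene_lengths) == nrow(cm))
      note("counts", "lengths_positive", all(gene_lengths > 0))
    }
  }
  if (!length(rows)) return(tibble::tibble(input = character(0),
                                           check = character(0),
                                           ok = logical(0),
                                           detail = character(0)))
  dplyr::bind_rows(rows)
}
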