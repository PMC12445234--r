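#' Normalize a gene's full name for identity matching
#'
#' Case-folds, collapses whitespace, strips balanced parenthetical aliases
#' (including nested ones), and trims trailing punctuation. Used so that two
#' table rows refer to the same gene only when both the symbol and the
#' normalized full name agree — symbol-only matching would merge distinct
#' genes that share a symbol (e.g. two different ribosomal-protein entries
#' printed under the same symbol).
#'
#' @param name Character vector of gene names (`NA` becomes `""`).
#' @return Normalized names.
#' @export
#' @examples
#' normalize_gene_name("Ring Finger Protein 112 (also Zinc Finger Protein 179 (ZNF179))")
normalize_gene_name <- function(name) {
  name[is.na(name)] <- ""
  out <- tolower(name)
  # iteratively delete innermost parentheticals so nesting unwinds
  repeat {
    nxt <- gsub("\\([^()]*\\)", " ", out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  out <- gsub("\\s+", " ", out)
  out <- gsub("[ ,;:.]+$", "", out)
  trimws(out)
}

#' Gene identity key
#'
#' Combines the case-preserved symbol with the normalized full name. Two
#' records denote the same gene only if both components match.
#'
#' @param gene_symbol Non-empty gene symbol(s).
#' @param gene_name Full gene name(s); normalized internally.
#' @return Character key(s).
#' @export
#' @examples
#' gene_identity_key("Rpl19", "Ribosomal Protein L19")
gene_identity_key <- function(gene_symbol, gene_name) {
  if (any(is.na(gene_symbol) | gene_symbol == "")) {
    abort("gene_symbol must be non-empty")
  }
  paste(gene_symbol, normalize_gene_name(gene_name), sep = "|")
}

#' Read a differentially-expressed-gene table
#'
#' Parses a TSV in the published-table dialect (`gene_symbol`, `gene_name`,
#' `adjusted_p`, plus optional engine extras such as `log2_fold_change`).
#' Rows whose symbol is `Unknown` are retained but flagged `unnamed`.
#' Duplicate identity keys are an error.
#'
#' @param path TSV path.
#' @param region Brain region label (e.g. `"DG"`, `"BLA"`).
#' @param contrast Contrast label (`"SL_vs_SH"`, `"C_vs_SL"`, `"C_vs_SH"`).
#' @return A `deg_table` tibble with columns `gene_symbol`, `gene_name`,
#'   `adjusted_p`, `unnamed`, `identity_key` (plus any extras) and
#'   attributes `region` and `contrast`.
#' @export
read_deg_table <- function(path, region, contrast) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(c("gene_symbol", "gene_name", "adjusted_p"), header)
  if (length(missing)) {
    abort(paste0("DEG table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_symbol = readr::col_character(),
    gene_name = readr::col_character(),
    adjusted_p = readr::col_double(),
    .default = readr::col_guess()), na = character(), progress = FALSE)
  as_deg_table(df, region, contrast)
}

#' @rdname read_deg_table
#' @param records In-memory data frame in the same dialect.
#' @export
as_deg_table <- function(records, region, contrast) {
  df <- tibble::as_tibble(records)
  assert_columns(df, c("gene_symbol", "gene_name", "adjusted_p"), "DEG table")
  if (nrow(df)) {
    if (any(df$adjusted_p < 0 | df$adjusted_p > 1, na.rm = TRUE)) {
      abort("adjusted_p must lie in [0, 1]")
    }
    df$unnamed <- df$gene_symbol == "Unknown" | is.na(df$gene_name) |
      df$gene_name %in% c("", "NA")
    df$identity_key <- gene_identity_key(df$gene_symbol, df$gene_name)
    dup <- df$identity_key[duplicated(df$identity_key)]
    if (length(dup)) {
      abort(paste0("duplicate gene identity key(s): ", paste(unique(dup), collapse = ", ")))
    }
  } else {
    df$unnamed <- logical(0)
    df$identity_key <- character(0)
  }
  attr(df, "region") <- region
  attr(df, "contrast") <- contrast
  class(df) <- c("deg_table", class(df))
  df
}

check_same_region <- function(a, b) {
  ra <- attr(a, "region"); rb <- attr(b, "region")
  if (!is.null(ra) && !is.null(rb) && !identical(ra, rb)) {
    abort(sprintf("DEG tables come from different regions (%s vs %s)", ra, rb))
  }
  ra %||% rb
}

overlap_signature <- function(a, b, set_name, direction_consistent = FALSE) {
  keys <- intersect(a$identity_key, b$identity_key)
  out <- a[a$identity_key %in% keys,
           intersect(c("gene_symbol", "gene_name", "identity_key",
                       "adjusted_p"), names(a))]
  if (direction_consistent &&
      all(c("log2_fold_change") %in% names(a)) &&
      all(c("log2_fold_change") %in% names(b))) {
    dir_b <- setNames(sign(b$log2_fold_change), b$identity_key)
    same <- sign(a$log2_fold_change[match(out$identity_key, a$identity_key)]) ==
      dir_b[out$identity_key]
    out <- out[same, ]
  }
  stopifnot(all(out$identity_key %in% a$identity_key),
            all(out$identity_key %in% b$identity_key))
  attr(out, "signature") <- set_name
  attr(out, "region") <- check_same_region(a, b)
  attr(out, "provenance") <- c(attr(a, "contrast") %||% NA_character_,
                               attr(b, "contrast") %||% NA_character_)
  out
}

#' Resilience gene signature
#'
#' Genes shared between the stress-low vs. stress-high and control vs.
#' stress-low DEG tables, matched by identity key. These genes separate
#' resilient animals from both the control and the vulnerable group. The
#' overlap is set-based (fold-change direction ignored) by default;
#' `direction_consistent = TRUE` additionally requires matching
#' fold-change signs when both tables carry `log2_fold_change`.
#'
#' @param deg_slsh DEG table for the stress-low vs. stress-high contrast.
#' @param deg_csl DEG table for the control vs. stress-low contrast.
#' @param direction_consistent Require consistent fold-change direction.
#' @return A tibble of overlapping genes with attributes `signature`,
#'   `region` and `provenance` (the two parent contrasts). Both tables must
#'   come from the same region.
#' @export
resilience_signature <- function(deg_slsh, deg_csl,
                                 direction_consistent = FALSE) {
  overlap_signature(deg_slsh, deg_csl, "resilience", direction_consistent)
}

#' Susceptibility gene signature
#'
#' Genes shared between the stress-low vs. stress-high and control vs.
#' stress-high DEG tables — genes whose expression separates vulnerable
#' animals from both other groups.
#'
#' @param deg_slsh DEG table for the stress-low vs. stress-high contrast.
#' @param deg_csh DEG table for the control vs. stress-high contrast.
#' @inheritParams resilience_signature
#' @return As [resilience_signature()].
#' @export
susceptibility_signature <- function(deg_slsh, deg_csh,
                                     direction_consistent = FALSE) {
  overlap_signature(deg_slsh, deg_csh, "susceptibility", direction_consistent)
}

#' Leave-one-out outlier-robustness flag for a significant gene
#'
#' A differential-expression call is "outlier-driven" when it hinges on a
#' single sample. The rule: find the sample with the largest absolute
#' within-group z-score of the gene's log2(normalized count + 1) values,
#' rerun the test without it, and flag the gene if it is no longer
#' significant at the working threshold. Flagged genes are disregarded from
#' signatures.
#'
#' @param counts Count matrix, genes x samples.
#' @param groups Two-group labels, one per sample.
#' @param gene Row name (or index) of the gene; must be significant in the
#'   full data.
#' @param alpha Significance threshold.
#' @return A logical flag with attributes `removed_sample` and
#'   `adj_p_after`. If removal leaves a group with fewer than 2 samples the
#'   gene is flagged with a degenerate-design warning.
#' @export
outlier_driven_flag <- function(counts, groups, gene, alpha = 0.05) {
  counts <- as.matrix(counts)
  full <- de_test(counts, groups, alpha = alpha)
  idx <- if (is.character(gene)) match(gene, full$gene_symbol) else as.integer(gene)
  if (is.na(idx) || idx < 1 || idx > nrow(full)) abort("gene not found")
  if (!full$significant[idx]) {
    abort("gene is not significant in the full data; the outlier filter applies only to significant calls")
  }
  q <- sweep(counts, 2, attr(full, "size_factors"), "/")
  x <- log2p1(q[idx, ])
  z <- unlist(lapply(unique(groups), function(g) {
    xi <- x[groups == g]
    s <- sd(xi)
    if (is.na(s) || s == 0) setNames(rep(0, length(xi)), names(xi))
    else (xi - mean(xi)) / s
  }))
  z <- z[colnames(counts)]
  drop <- which.max(abs(z))
  kept <- setdiff(seq_len(ncol(counts)), drop)
  if (min(table(groups[kept])) < 2L) {
    warn("removing the outlier sample leaves a group with < 2 samples; flagging by default")
    out <- TRUE
    attr(out, "removed_sample") <- colnames(counts)[drop]
    attr(out, "adj_p_after") <- NA_real_
    return(out)
  }
  refit <- de_test(counts[, kept, drop = FALSE], groups[kept], alpha = alpha)
  out <- !refit$significant[idx]
  attr(out, "removed_sample") <- colnames(counts)[drop]
  attr(out, "adj_p_after") <- refit$adj_p[idx]
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared statistic combines the z-transformed sample skewness
#' (D'Agostino) and kurtosis (Anscombe-Glynn) and is referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector with at least 8 observations.
#' @return A list of class `htest` with `statistic` (K-squared) and
#'   `p.value`.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) abort("D'Agostino-Pearson test needs at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) abort("zero variance")
  # skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  structure(list(statistic = c(`K-squared` = k2),
                 p.value = pchisq(k2, df = 2, lower.tail = FALSE),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Correlate single-gene expression with composite behavior scores
#'
#' Pearson correlation of log2(TPM + 1) expression against composite
#' scores, with a normality report (Shapiro-Wilk and D'Agostino-Pearson) on
#' the expression values — the workflow used to relate a susceptibility
#' gene's expression to anxiety-like behavior.
#'
#' @param log_expr Transformed expression values (one gene, one value per
#'   animal; at least 3).
#' @param scores Composite scores, same length and order.
#' @return A list of class `cbc_cor`: `correlation` tibble (`r`, `p_value`,
#'   `n`, `df`) and `normality` tibble (`test`, `statistic`, `p_value`).
#'   The normality rows are `NA` when n < 8 (too small for the omnibus
#'   test).
#' @export
expression_behavior_correlation <- function(log_expr, scores) {
  if (length(log_expr) != length(scores)) {
    abort("expression and score vectors must have equal length")
  }
  if (length(log_expr) < 3L) abort("need at least 3 paired values")
  corr <- pearson_correlation(log_expr, scores)
  sw <- shapiro.test(log_expr)
  da <- if (length(log_expr) >= 8L) dagostino_test(log_expr) else NULL
  normality <- tibble::tibble(
    test = c("shapiro_wilk", "dagostino_pearson"),
    statistic = c(unname(sw$statistic),
                  if (is.null(da)) NA_real_ else unname(da$statistic)),
    p_value = c(sw$p.value, if (is.null(da)) NA_real_ else da$p.value))
  structure(list(correlation = corr, normality = normality),
            class = "cbc_cor")
}

#' @export
print.cbc_cor <- function(x, ...) {
  cat(sprintf("<cbc_cor> r = %.4f, p = %.4g, n = %d\n",
              x$correlation$r, x$correlation$p_value, x$correlation$n))
  cat("normality:\n")
  print(x$normality)
  invisible(x)
}
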