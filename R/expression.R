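#' Convert raw counts to transcripts per million
#'
#' Length-normalizes each gene's counts to a rate (count / length) and
#' rescales each sample so its rates sum to one million:
#' `tpm[g, s] = 1e6 * (c[g, s] / l[g]) / sum_g'(c[g', s] / l[g'])`.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @param gene_lengths Positive gene lengths (bp), one per row of `counts`.
#' @return A TPM matrix with the same dimnames; every column sums to 1e6.
#' @export
#' @examples
#' counts_to_tpm(matrix(c(10, 10), 2, 1), c(1000, 2000))
counts_to_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts)) {
    abort("gene_lengths must have one entry per gene (row)")
  }
  if (any(gene_lengths <= 0)) abort("gene_lengths must be positive")
  if (any(counts < 0)) abort("counts must be non-negative")
  rate <- counts / gene_lengths
  denom <- colSums(rate)
  zero <- which(denom == 0)
  if (length(zero)) {
    nm <- colnames(counts)[zero] %||% as.character(zero)
    abort(paste0("sample(s) with all-zero counts: ", paste(nm, collapse = ", ")))
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Shifted log2 transform
#'
#' Elementwise `log2(x + 1)`, the variance-stabilizing transform applied to
#' TPM values before correlation and clustering.
#'
#' @param x Non-negative numeric vector or matrix.
#' @return Transformed values of the same shape.
#' @export
#' @examples
#' log2p1(c(0, 1, 3))  # 0 1 2
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("log2p1 requires non-negative input")
  log2(x + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p_values P-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1] with no NA")
  }
  p.adjust(p_values, method = "BH")
}

# median-of-ratios size factors with a total-count fallback when too few
# genes are expressed in every sample
size_factors <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (sum(ok) >= 10) {
    geo <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
    sf <- apply(counts[ok, , drop = FALSE] / geo, 2, median)
  } else {
    tot <- colSums(counts)
    if (any(tot == 0)) abort("cannot normalize: a sample has zero total counts")
    sf <- tot / mean(tot)
  }
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for differential expression
#'
#' A documented, replaceable differential-expression engine producing DEG
#' tables for the signature-overlap stage. Counts are normalized with
#' median-of-ratios size factors (total-count fallback); per-gene
#' dispersions are estimated by method of moments on the pooled
#' within-group variance, shrunk 50% toward the trimmed-mean common
#' dispersion and floored at that common value (the floor keeps genes with
#' under-estimated dispersion from dominating the discovery list at n = 3
#' per group); significance is a Wald test on the log2 ratio of normalized
#' group means (0.5 pseudocount) with Benjamini-Hochberg adjustment.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param groups Per-sample group labels; exactly two distinct values. The
#'   first level (factor order) is the reference; `log2_fold_change` > 0
#'   means higher expression in the second group.
#' @param gene_names Optional per-gene display names.
#' @param alpha Adjusted-p significance threshold.
#' @param contrast Optional label for the comparison (e.g. `"SL_vs_SH"`);
#'   defaults to `"<ref>_vs_<other>"`.
#' @return A tibble of class `cbc_de` with one row per gene: `gene_symbol`,
#'   `gene_name`, `base_mean`, `log2_fold_change`, `p_value`, `adj_p`,
#'   `significant`, `direction` (`up`/`down` in the second group).
#'   Attributes: `contrast`, `alpha`, `groups`, `common_dispersion`,
#'   `size_factors`.
#' @export
de_test <- function(counts, groups, gene_names = NULL, alpha = 0.05,
                    contrast = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) {
    abort("groups must have one label per sample (column)")
  }
  lev <- unique(groups)
  if (length(lev) != 2L) abort("de_test compares exactly two groups")
  g1 <- which(groups == lev[1]); g2 <- which(groups == lev[2])
  if (length(g1) < 2L || length(g2) < 2L) {
    abort("each group needs at least 2 samples")
  }
  gene_ids <- rownames(counts) %||% sprintf("gene_%d", seq_len(nrow(counts)))
  gene_names <- gene_names %||% gene_ids

  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(q[, g1, drop = FALSE]); m2 <- rowMeans(q[, g2, drop = FALSE])
  v1 <- apply(q[, g1, drop = FALSE], 1, var)
  v2 <- apply(q[, g2, drop = FALSE], 1, var)
  vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mw <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp <- pmax(0, (vw - mw) / mw^2)
  disp[!is.finite(disp)] <- 0
  use <- mw > 1
  common <- if (any(use)) mean(disp[use], trim = 0.1) else 0
  if (!is.finite(common)) common <- 0
  disp_s <- pmax(0.5 * disp + 0.5 * common, common)

  m1p <- m1 + 0.5; m2p <- m2 + 0.5
  lfc <- log2(m2p / m1p)
  se2 <- (m1p + disp_s * m1p^2) / (n1 * m1p^2 * log(2)^2) +
         (m2p + disp_s * m2p^2) / (n2 * m2p^2 * log(2)^2)
  z <- lfc / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  adj <- bh_adjust(p)

  out <- tibble::tibble(gene_symbol = gene_ids, gene_name = gene_names,
                        base_mean = unname(mw),
                        log2_fold_change = unname(lfc),
                        p_value = unname(p), adj_p = unname(adj),
                        significant = unname(adj < alpha),
                        direction = unname(ifelse(lfc >= 0, "up", "down")))
  attr(out, "contrast") <- contrast %||% paste0(lev[1], "_vs_", lev[2])
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- lev
  attr(out, "common_dispersion") <- common
  attr(out, "size_factors") <- sf
  class(out) <- c("cbc_de", class(out))
  out
}

#' Flag samples that fail to cluster in principal-component space
#'
#' Projects samples onto the first two principal components of the
#' transformed expression matrix and flags any sample whose distance to its
#' nearest neighbor exceeds `k` times the median nearest-neighbor distance —
#' the "does not cluster with any other samples" exclusion rule.
#'
#' @param log_tpm Transformed expression matrix, genes x samples (at least
#'   3 samples).
#' @param k Multiplier of the median nearest-neighbor distance
#'   (`Inf` disables flagging).
#' @return Character vector of flagged sample names (possibly empty).
#' @export
pca_outlier_flag <- function(log_tpm, k = 3) {
  log_tpm <- as.matrix(log_tpm)
  ns <- ncol(log_tpm)
  if (ns < 3L) abort("need at least 3 samples for PCA outlier flagging")
  keep <- apply(log_tpm, 1, var) > 0
  scores <- if (any(keep)) {
    pr <- prcomp(t(log_tpm[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
    pr$x[, seq_len(min(2, ncol(pr$x))), drop = FALSE]
  } else matrix(0, ns, 1)
  d <- as.matrix(stats::dist(scores))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  med <- median(nn)
  flagged <- which(nn > k * med)
  (colnames(log_tpm) %||% as.character(seq_len(ns)))[flagged]
}

#' @export
print.cbc_de <- function(x, ...) {
  cat(sprintf("<cbc_de> contrast %s: %d genes, %d significant at adj p < %g\n",
              attr(x, "contrast"), nrow(x), sum(x$significant),
              attr(x, "alpha")))
  NextMethod()
}
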