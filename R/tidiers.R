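#' Tidy a differential-expression result
#'
#' @param x A `cbc_de` object from [de_test()].
#' @param ... Unused.
#' @return A plain tibble, one row per gene.
#' @method tidy cbc_de
#' @export
tidy.cbc_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cbc_de")
  tibble::as_tibble(out)
}

#' One-row summary of a differential-expression result
#'
#' @inheritParams tidy.cbc_de
#' @return A tibble with `contrast`, `n_genes`, `n_significant`, `alpha`,
#'   `common_dispersion`.
#' @method glance cbc_de
#' @export
glance.cbc_de <- function(x, ...) {
  tibble::tibble(contrast = attr(x, "contrast"),
                 n_genes = nrow(x),
                 n_significant = sum(x$significant),
                 alpha = attr(x, "alpha"),
                 common_dispersion = attr(x, "common_dispersion"))
}

#' Tidy an expression-behavior correlation
#'
#' @param x A `cbc_cor` from [expression_behavior_correlation()].
#' @param ... Unused.
#' @return The correlation tibble (`r`, `p_value`, `n`, `df`).
#' @method tidy cbc_cor
#' @export
tidy.cbc_cor <- function(x, ...) x$correlation

#' One-row summary of an expression-behavior correlation
#'
#' @inheritParams tidy.cbc_cor
#' @return A tibble with the correlation plus both normality p-values.
#' @method glance cbc_cor
#' @export
glance.cbc_cor <- function(x, ...) {
  dplyr::bind_cols(
    x$correlation,
    tibble::tibble(
      shapiro_p = x$normality$p_value[x$normality$test == "shapiro_wilk"],
      dagostino_p = x$normality$p_value[x$normality$test == "dagostino_pearson"]))
}
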