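#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) to share the same distribution: each value is
#' replaced by the row-mean of the column-sorted matrix at its rank, with
#' ties within a column receiving the mean of the reference values at the
#' tied ranks. An upper-quartile alternative is available: columns are
#' rescaled so their 75th percentiles agree (set to the mean 75th
#' percentile), the usual single-factor scaling used on arrays.
#'
#' @param expr A matrix tibble: feature id in the first column, one numeric
#'   column per sample. No missing values.
#' @param method `"quantile"` (default) or `"upper_quartile"`.
#' @return A matrix tibble of the same shape.
#' @examples
#' toy <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                       s1 = c(1, 3, 5, 7), s2 = c(2, 4, 6, 8))
#' quantile_normalize(toy)
#' @export
quantile_normalize <- function(expr, method = c("quantile", "upper_quartile")) {
  method <- match.arg(method)
  m <- mat_from_tbl(expr)
  if (anyNA(m)) rlang::abort("missing values: impute or drop before normalization")
  if (method == "quantile") {
    if (ncol(m) >= 2) m <- limma::normalizeQuantiles(m, ties = TRUE)
  } else {
    q3 <- apply(m, 2, stats::quantile, probs = 0.75, names = FALSE)
    if (any(q3 == 0)) rlang::abort("a column has zero 75th percentile")
    m <- sweep(m, 2, mean(q3) / q3, `*`)
  }
  out <- tbl_from_mat(m, names(expr)[1])
  out[[1]] <- expr[[1]]
  out
}

#' Differential expression by two-sample t-test with BH correction
#'
#' Per feature: equal-variance two-sample t-test on log2 values
#' (case - control), Benjamini-Hochberg adjustment across all tested
#' features, and a joint call `is_de` requiring `|log2FC| > lfc_cut` *and*
#' `fdr < fdr_cut` (both strict). Intended to run on quantile-normalized
#' log2 intensities; run mRNAs and lncRNAs separately so the FDR is
#' controlled within each RNA type. With the tiny group sizes typical of
#' array pilot cohorts (n = 3 vs 3) the plain t-test is noisier than a
#' moderated one; see the package vignette for this deliberate
#' simplification.
#'
#' @param expr A matrix tibble of expression values.
#' @param samples A data frame with columns `sample_id` and `group`.
#' @param lfc_cut,fdr_cut Call thresholds (defaults 1 and 0.05, strict).
#' @param ref,case Group labels (defaults `"ctrl"` and `"uc"`).
#' @param log2_input Set `FALSE` for linear intensities; `log2(x + 1)` is
#'   applied first.
#' @param var_equal Equal-variance (pooled) t-test by default; `FALSE` gives
#'   Welch.
#' @return A tibble sorted by `fdr` then `|log2fc|` (descending):
#'   `feature_id`, `mean_log2_ctrl`, `mean_log2_case`, `log2fc`, `t_stat`,
#'   `p`, `fdr`, `is_de`, `direction` (`up`/`down`/`none`). Features with
#'   zero variance in both groups and equal means get `p = 1`.
#' @export
differential_expression <- function(expr, samples, lfc_cut = 1.0,
                                    fdr_cut = 0.05, ref = "ctrl",
                                    case = "uc", log2_input = TRUE,
                                    var_equal = TRUE) {
  m <- mat_from_tbl(expr)
  if (!log2_input) m <- log2(m + 1)
  ids <- check_groups(samples, colnames(m), ref, case)
  tt <- row_t_test(m[, ids$ref, drop = FALSE], m[, ids$case, drop = FALSE],
                   var_equal = var_equal)
  res <- tibble::tibble(
    feature_id = rownames(m),
    mean_log2_ctrl = tt$mean_ref,
    mean_log2_case = tt$mean_case,
    log2fc = tt$diff,
    t_stat = tt$t_stat,
    p = tt$p,
    fdr = p.adjust(tt$p, method = "BH")
  ) |>
    dplyr::mutate(
      is_de = abs(.data$log2fc) > lfc_cut & .data$fdr < fdr_cut,
      direction = dplyr::case_when(
        .data$is_de & .data$log2fc > 0 ~ "up",
        .data$is_de & .data$log2fc < 0 ~ "down",
        .default = "none"
      )
    ) |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$log2fc)))
  res
}

#' Label-swap sanity check for the differential expression stage
#'
#' Swapping the group labels must negate every log2 fold change and leave
#' every p-value unchanged; this harness verifies that antisymmetry to a
#' tolerance.
#'
#' @inheritParams differential_expression
#' @param tol Tolerance on the antisymmetry (default 1e-12).
#' @return A one-row tibble: `max_abs_log2fc_sum` (largest
#'   `|log2fc + log2fc_swapped|`), `max_abs_p_diff`, and `ok`.
#' @export
label_swap_check <- function(expr, samples, ref = "ctrl", case = "uc",
                             log2_input = TRUE, tol = 1e-12) {
  de1 <- differential_expression(expr, samples, ref = ref, case = case,
                                 log2_input = log2_input) |>
    dplyr::arrange(.data$feature_id)
  de2 <- differential_expression(expr, samples, ref = case, case = ref,
                                 log2_input = log2_input) |>
    dplyr::arrange(.data$feature_id)
  lfc_sum <- max(abs(de1$log2fc + de2$log2fc))
  p_diff <- max(abs(de1$p - de2$p))
  tibble::tibble(max_abs_log2fc_sum = lfc_sum, max_abs_p_diff = p_diff,
                 ok = lfc_sum <= tol & p_diff <= tol)
}
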