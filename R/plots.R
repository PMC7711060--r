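#' Volcano plot of a differential expression result
#'
#' @param de Output of [differential_expression()].
#' @param lfc_cut,fdr_cut Thresholds drawn as guides (defaults 1, 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_cut = 1.0, fdr_cut = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$fdr),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(fdr_cut),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(up = "#d7301f", down = "#2b8cbe", none = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Promoter class composition by biotype
#'
#' @param classes Output of [classify_promoters()] with a `biotype` column.
#' @return A ggplot object.
#' @export
plot_promoter_classes <- function(classes) {
  ggplot2::ggplot(classes, ggplot2::aes(x = .data$biotype,
                                        fill = .data$cls)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1) +
    ggplot2::labs(x = NULL, y = "promoters", fill = "CpG class") +
    ggplot2::theme_minimal()
}

#' Promoter methylation by CpG class and group
#'
#' Boxplots of promoter mean beta per CpG class, split by sample group -
#' the view in which high-CpG promoters sit lowest and low-CpG promoters
#' highest.
#'
#' @param promoter_meth Output of [promoter_methylation()].
#' @param classes Output of [classify_promoters()].
#' @param samples Data frame with `sample_id` and `group`.
#' @return A ggplot object.
#' @export
plot_beta_by_class <- function(promoter_meth, classes, samples) {
  long <- promoter_meth |>
    tidyr::pivot_longer(-1, names_to = "sample_id", values_to = "beta") |>
    dplyr::inner_join(samples[c("sample_id", "group")], by = "sample_id") |>
    dplyr::inner_join(classes[c("gene_id", "cls")], by = "gene_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cls, y = .data$beta,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "promoter CpG class", y = "promoter mean beta",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Degree distribution of a co-expression network
#'
#' @param object A `coexpression_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_network <- function(object, ...) {
  ggplot2::ggplot(object$degrees,
                  ggplot2::aes(x = .data$degree, fill = .data$type)) +
    ggplot2::geom_histogram(binwidth = 1, position = "dodge",
                            colour = "white") +
    ggplot2::labs(x = "node degree", y = "nodes", fill = NULL) +
    ggplot2::theme_minimal()
}
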