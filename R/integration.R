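#' Intersect differential expression with DMP calls into candidate markers
#'
#' A feature becomes a candidate marker iff it is differentially expressed,
#' its promoter carries a DMP call, and the two directions are concordant
#' with promoter-methylation repression: up-regulated with a hypo-methylated
#' promoter, or down-regulated with a hyper-methylated promoter. Discordant
#' combinations are excluded by construction. The join is by gene id;
#' features that are DE but lack promoter methylation data simply cannot
#' become candidates (they remain countable via [integration_report()]).
#'
#' @param de_results Output of [differential_expression()] (one RNA type, or
#'   several row-bound with distinct ids). A `biotype` column is carried
#'   through when present.
#' @param dmp_results Output of [identify_dmps()].
#' @return A tibble of candidate markers: `feature_id`, (`biotype`,)
#'   `de_direction` (`up`/`down`), `dmp_call` (`hypo`/`hyper`), `log2fc`,
#'   `delta_beta`, sorted by `feature_id`.
#' @export
integrate_markers <- function(de_results, dmp_results) {
  if (anyDuplicated(de_results$feature_id)) {
    rlang::abort("duplicate feature_id in DE results")
  }
  if (anyDuplicated(dmp_results$gene_id)) {
    rlang::abort("duplicate gene_id in DMP results")
  }
  de <- de_results |>
    dplyr::filter(.data$is_de) |>
    dplyr::select(dplyr::any_of(c("feature_id", "biotype")),
                  de_direction = "direction", "log2fc")
  dmp <- dmp_results |>
    dplyr::filter(.data$call != "none") |>
    dplyr::select(feature_id = "gene_id", dmp_call = "call", "delta_beta") |>
    dplyr::mutate(dmp_call = as.character(.data$dmp_call))
  de |>
    dplyr::inner_join(dmp, by = "feature_id") |>
    dplyr::filter(
      (.data$de_direction == "up" & .data$dmp_call == "hypo") |
        (.data$de_direction == "down" & .data$dmp_call == "hyper")
    ) |>
    dplyr::arrange(.data$feature_id)
}

#' Summarise the integration stage
#'
#' Counts candidates per biotype and concordance category and the fraction of
#' DE features retained after the joint methylation filter.
#'
#' @param candidates Output of [integrate_markers()]; if it lacks a
#'   `biotype` column all features are reported as one group.
#' @param de_results Optional DE table(s) used to report the retention
#'   fraction.
#' @return A list with `by_category` (tibble: `biotype`, `de_direction`,
#'   `dmp_call`, `n`), `by_biotype` (tibble: `biotype`, `n_candidates`, and
#'   when `de_results` is given `n_de` and `pct_of_de`), and `total`.
#' @export
integration_report <- function(candidates, de_results = NULL) {
  cand <- candidates
  if (!"biotype" %in% names(cand)) cand$biotype <- "all"
  by_category <- cand |>
    dplyr::count(.data$biotype, .data$de_direction, .data$dmp_call)
  by_biotype <- cand |>
    dplyr::count(.data$biotype, name = "n_candidates")
  if (!is.null(de_results)) {
    de <- de_results
    if (!"biotype" %in% names(de)) de$biotype <- "all"
    n_de <- de |>
      dplyr::filter(.data$is_de) |>
      dplyr::count(.data$biotype, name = "n_de")
    by_biotype <- by_biotype |>
      dplyr::full_join(n_de, by = "biotype") |>
      dplyr::mutate(
        dplyr::across(c("n_candidates", "n_de"), ~ tidyr::replace_na(.x, 0L)),
        pct_of_de = crosstab_pct(.data$n_candidates, .data$n_de)
      )
  }
  list(by_category = by_category, by_biotype = by_biotype,
       total = nrow(cand))
}
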