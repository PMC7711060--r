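#' Assign CpG sites to promoter intervals
#'
#' A site belongs to a promoter iff `start <= pos < end` (0-based half-open,
#' matching the site manifest). A site overlapping several promoters is
#' assigned to all of them. Sites on chromosomes absent from the promoter
#' table yield no assignment; genes without any site are reported so they can
#' be excluded from downstream differential methylation.
#'
#' @param sites Site manifest: `site_id`, `chrom`, `pos` (0-based).
#' @param promoters Promoter table: `gene_id`, `chrom`, `start`, `end`.
#' @param quiet Suppress informational messages.
#' @return A tibble `gene_id`, `site_id`, one row per assignment.
#' @export
map_sites_to_promoters <- function(sites, promoters, quiet = FALSE) {
  stopifnot(all(c("site_id", "chrom", "pos") %in% names(sites)),
            all(c("gene_id", "chrom", "start", "end") %in% names(promoters)))
  if (anyDuplicated(sites$site_id)) rlang::abort("duplicate site_id in manifest")
  out <- vector("list", 0)
  for (chr in unique(promoters$chrom)) {
    s <- sites[sites$chrom == chr, ]
    p <- promoters[promoters$chrom == chr, ]
    if (nrow(s) == 0 || nrow(p) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s$pos + 1L, s$pos + 1L),
      IRanges::IRanges(p$start + 1L, p$end)  # half-open -> 1-based closed
    )
    out[[chr]] <- tibble::tibble(
      gene_id = p$gene_id[S4Vectors::subjectHits(hits)],
      site_id = s$site_id[S4Vectors::queryHits(hits)]
    )
  }
  map <- dplyr::bind_rows(out)
  if (!quiet) {
    off_chrom <- sum(!sites$chrom %in% promoters$chrom)
    if (off_chrom > 0) {
      rlang::inform(sprintf("%d site(s) on chromosomes without promoters", off_chrom))
    }
    n_empty <- sum(!promoters$gene_id %in% map$gene_id)
    if (n_empty > 0) {
      rlang::inform(sprintf("%d promoter(s) with zero CpG sites", n_empty))
    }
  }
  dplyr::arrange(map, .data$gene_id, .data$site_id)
}

#' Promoter-level methylation: mean beta over promoter CpG sites
#'
#' The methylation level of a promoter in a sample is the arithmetic mean of
#' the beta values of all CpG sites in that promoter, skipping missing
#' values; the result is missing only when every site is missing for that
#' sample.
#'
#' @param beta A matrix tibble: `site_id` x samples, values in \[0, 1\],
#'   missing allowed.
#' @param site_map Output of [map_sites_to_promoters()].
#' @return A matrix tibble: `gene_id` x samples of promoter mean betas.
#' @export
promoter_methylation <- function(beta, site_map) {
  if (nrow(site_map) == 0) rlang::abort("empty site map")
  m <- mat_from_tbl(beta)
  ok <- site_map$site_id %in% rownames(m)
  if (!all(ok)) {
    rlang::warn(sprintf("%d mapped site(s) missing from the beta matrix",
                        sum(!ok)))
    site_map <- site_map[ok, ]
  }
  v <- m[site_map$site_id, , drop = FALSE]
  present <- !is.na(v)
  v[!present] <- 0
  sums <- rowsum(v, site_map$gene_id)
  cnts <- rowsum(present + 0, site_map$gene_id)
  means <- sums / cnts
  means[cnts == 0] <- NA_real_
  tbl_from_mat(means, "gene_id")
}

#' Call differentially methylated promoters by rank
#'
#' Per promoter, an equal-variance two-sample t-statistic (case - control) on
#' promoter mean betas; promoters are then sorted by the signed statistic and
#' the extreme `tail_fraction` at each end are called: the top tail `hyper`
#' (more methylated in the case group), the bottom tail `hypo`. Tail size is
#' `k = round_half_up(tail_fraction * n)`, symmetric; ties are broken by
#' `|delta_beta|` (larger wins the tail) then `gene_id`. When a `genes` table
#' with biotypes is supplied, ranking is performed separately within mRNA-
#' and lncRNA-gene promoters. This is a rank-based definition: it always
#' calls `2k` promoters per stratum regardless of effect size.
#'
#' @param promoter_meth A matrix tibble of promoter mean betas
#'   ([promoter_methylation()]).
#' @param samples Data frame with `sample_id`, `group`.
#' @param genes Optional data frame `gene_id`, `biotype` for per-biotype
#'   ranking.
#' @param tail_fraction Fraction called at each extreme (default 0.05).
#' @param ref,case Group labels (defaults `"ctrl"`, `"uc"`).
#' @param stat Ranking statistic: signed `"t_stat"` (default) or
#'   `"delta_beta"`.
#' @param var_equal Pooled-variance t by default; `FALSE` for Welch.
#' @param site_map Optional [map_sites_to_promoters()] output used to report
#'   `n_sites`.
#' @return A tibble with one row per analysed promoter: `gene_id`,
#'   (`biotype`,) `n_sites`, `mean_beta_ctrl`, `mean_beta_case`,
#'   `delta_beta`, `t_stat`, `p`, `rank_fraction` (ascending rank of the
#'   ranking statistic divided by stratum size) and `call`
#'   (`hyper`/`hypo`/`none`). Promoters missing a whole group are excluded
#'   with a message.
#' @export
identify_dmps <- function(promoter_meth, samples, genes = NULL,
                          tail_fraction = 0.05, ref = "ctrl", case = "uc",
                          stat = c("t_stat", "delta_beta"), var_equal = TRUE,
                          site_map = NULL) {
  stat <- match.arg(stat)
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    rlang::abort("tail_fraction must lie in (0, 0.5) for disjoint tails")
  }
  m <- mat_from_tbl(promoter_meth)
  ids <- check_groups(samples, colnames(m), ref, case)
  m_ref <- m[, ids$ref, drop = FALSE]
  m_case <- m[, ids$case, drop = FALSE]

  whole_group_missing <- rowSums(!is.na(m_ref)) == 0 | rowSums(!is.na(m_case)) == 0
  if (any(whole_group_missing)) {
    rlang::inform(sprintf(
      "%d promoter(s) excluded: promoter mean missing in a whole group",
      sum(whole_group_missing)))
    m_ref <- m_ref[!whole_group_missing, , drop = FALSE]
    m_case <- m_case[!whole_group_missing, , drop = FALSE]
  }
  # per-promoter t on available samples (usually complete -> vectorised path)
  if (anyNA(m_ref) || anyNA(m_case)) {
    tt <- purrr::map(seq_len(nrow(m_ref)), function(i) {
      x <- m_ref[i, ][!is.na(m_ref[i, ])]
      y <- m_case[i, ][!is.na(m_case[i, ])]
      row_t_test(matrix(x, 1), matrix(y, 1), var_equal = var_equal)
    }) |> purrr::list_rbind()
  } else {
    tt <- row_t_test(m_ref, m_case, var_equal = var_equal)
  }
  res <- tibble::tibble(
    gene_id = rownames(m_ref),
    mean_beta_ctrl = tt$mean_ref,
    mean_beta_case = tt$mean_case,
    delta_beta = tt$diff,
    t_stat = tt$t_stat,
    p = tt$p
  )
  if (!is.null(site_map)) {
    ns <- dplyr::count(site_map, .data$gene_id, name = "n_sites")
    res <- dplyr::left_join(res, ns, by = "gene_id")
  } else {
    res$n_sites <- NA_integer_
  }
  if (!is.null(genes)) {
    res <- dplyr::left_join(res, genes[c("gene_id", "biotype")], by = "gene_id")
    if (anyNA(res$biotype)) {
      rlang::abort("genes table lacks a biotype for some promoters")
    }
  } else {
    res$biotype <- "all"
  }

  call_stratum <- function(d) {
    n <- nrow(d)
    if (n < 20) {
      rlang::abort(sprintf(
        "need >= 20 promoters per stratum for tail calling (got %d)", n))
    }
    k <- round_half_up(tail_fraction * n)
    s <- d[[stat]]
    hi <- order(-s, -abs(d$delta_beta), d$gene_id)[seq_len(k)]
    lo <- order(s, -abs(d$delta_beta), d$gene_id)[seq_len(k)]
    d$call <- "none"
    d$call[hi] <- "hyper"
    d$call[lo] <- "hypo"
    d$rank_fraction <- rank(s, ties.method = "average") / n
    d
  }
  res <- res |>
    dplyr::group_by(.data$biotype) |>
    dplyr::group_modify(~ call_stratum(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(call = factor(.data$call, levels = c("hyper", "hypo", "none"))) |>
    dplyr::relocate("gene_id", "biotype", "n_sites") |>
    dplyr::arrange(.data$biotype, dplyr::desc(.data$t_stat))
  if (is.null(genes)) res$biotype <- NULL
  res
}

#' Cross-tabulate DMP calls against promoter CpG classes
#'
#' For each biotype x promoter-class cell: the number of promoters, the
#' hyper- and hypo-methylated DMP counts, and their percentages of the cell
#' total (2 decimals). Per-biotype totals are appended as `cls = "total"`
#' rows.
#'
#' @param dmps Output of [identify_dmps()].
#' @param classes Output of [classify_promoters()] with `biotype` (defines
#'   the totals; every DMP gene must appear here).
#' @return A tibble: `biotype`, `cls`, `total`, `hyper`, `hyper_pct`,
#'   `hypo`, `hypo_pct`.
#' @export
dmp_crosstab <- function(dmps, classes) {
  stopifnot(all(c("gene_id", "biotype", "cls") %in% names(classes)))
  if (!all(dmps$gene_id %in% classes$gene_id)) {
    rlang::abort("some DMP genes are missing from the classes table")
  }
  called <- dmps |>
    dplyr::filter(.data$call != "none") |>
    dplyr::select("gene_id", "call") |>
    dplyr::left_join(classes[c("gene_id", "biotype", "cls")], by = "gene_id")
  cells <- classes |>
    dplyr::count(.data$biotype, .data$cls, .drop = FALSE, name = "total")
  counts <- called |>
    dplyr::count(.data$biotype, .data$cls, .data$call, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "call", values_from = "n",
                       values_fill = 0L)
  for (col in c("hyper", "hypo")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  tab <- cells |>
    dplyr::left_join(counts[c("biotype", "cls", "hyper", "hypo")],
                     by = c("biotype", "cls")) |>
    dplyr::mutate(dplyr::across(c("hyper", "hypo"), ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::mutate(cls = as.character(.data$cls))
  totals <- tab |>
    dplyr::group_by(.data$biotype) |>
    dplyr::summarise(cls = "total", total = sum(.data$total),
                     hyper = sum(.data$hyper), hypo = sum(.data$hypo),
                     .groups = "drop")
  dplyr::bind_rows(tab, totals) |>
    dplyr::mutate(
      hyper_pct = crosstab_pct(.data$hyper, .data$total),
      hypo_pct = crosstab_pct(.data$hypo, .data$total)
    ) |>
    dplyr::relocate("biotype", "cls", "total", "hyper", "hyper_pct",
                    "hypo", "hypo_pct") |>
    dplyr::arrange(.data$biotype)
}

#' Percentage of a count, rounded to 2 decimals
#'
#' The report convention used by [dmp_crosstab()]: `count / total * 100`
#' rounded to two decimal places; 0 when the total is 0.
#'
#' @param count,total Non-negative counts (vectorised).
#' @return Numeric percentages.
#' @examples
#' crosstab_pct(119, 6067) # 1.96
#' @export
crosstab_pct <- function(count, total) {
  ifelse(total > 0, round(count / total * 100, 2), 0)
}
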