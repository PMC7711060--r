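#' Derive strand-aware promoter intervals around the TSS
#'
#' The promoter of a gene is taken as the interval from `upstream` bp upstream
#' to `downstream` bp downstream of its transcription start site (TSS),
#' strand-relative, in 0-based half-open coordinates. On the plus strand this
#' is `[tss - upstream, tss + downstream)`; on the minus strand
#' `[tss - downstream, tss + upstream)`. Intervals are clipped to
#' `[0, chrom_len)`.
#'
#' @param genes A data frame of gene models with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tss` (0-based), and optionally `biotype`.
#' @param chrom_len Chromosome length used for clipping. Either a single
#'   number (applied to all rows) or a named vector keyed by chromosome.
#'   Defaults to `Inf` (no right clipping).
#' @param upstream,downstream Extent of the promoter relative to the TSS, in
#'   bp (defaults 1500 and 500, giving 2-kb promoters).
#'
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, plus `biotype` when present in the input.
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("g1", "g2"), chrom = "chrS",
#'   strand = c("+", "-"), tss = c(10000L, 10000L)
#' )
#' derive_promoters(genes)
#' @export
derive_promoters <- function(genes, chrom_len = Inf,
                             upstream = 1500L, downstream = 500L) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "strand", "tss")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("genes is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    rlang::abort("strand must be '+' or '-'")
  }
  if (anyDuplicated(genes$gene_id)) rlang::abort("duplicate gene_id in genes")
  len_of <- function(chrom) {
    if (length(chrom_len) == 1 && is.null(names(chrom_len))) {
      rep(unname(chrom_len), length(chrom))
    } else {
      unname(chrom_len[chrom])
    }
  }
  cl <- len_of(genes$chrom)
  if (any(genes$tss < 0) || any(genes$tss >= cl)) {
    rlang::abort("tss must lie within [0, chrom_len)")
  }
  out <- genes |>
    dplyr::mutate(
      .chrom_len = len_of(.data$chrom),
      start = ifelse(.data$strand == "+",
                     .data$tss - upstream, .data$tss - downstream),
      end = ifelse(.data$strand == "+",
                   .data$tss + downstream, .data$tss + upstream),
      start = pmax(.data$start, 0),
      end = pmin(.data$end, .data$.chrom_len)
    )
  if (any(out$end <= out$start)) {
    bad <- out$gene_id[out$end <= out$start]
    rlang::abort(paste0("empty promoter interval after clipping for: ",
                        paste(head(bad, 5), collapse = ", ")))
  }
  keep <- intersect(c("gene_id", "chrom", "start", "end", "strand", "tss",
                      "biotype"), names(out))
  tibble::as_tibble(out[keep])
}

#' Observed/expected CpG ratio of a DNA window
#'
#' Computes the observed-over-expected CpG dinucleotide ratio
#' `(#CpG * L) / (#C * #G)` for a sequence of length `L`. Returns 0 when the
#' window contains no C or no G. `N` bases count toward the length but not
#' toward the C, G or CpG counts. The HCP/ICP/LCP thresholds used by
#' [classify_promoter()] (0.75 and 0.48) are defined on this scale.
#'
#' @param window A single DNA string (A/C/G/T/N, case-insensitive).
#' @return A non-negative number.
#' @examples
#' cpg_ratio("CGCG")       # 2.0
#' cpg_ratio("ATAT")       # 0
#' cpg_ratio("ACGTACGTGC") # ~2.22
#' @export
cpg_ratio <- function(window) {
  stopifnot(is.character(window), length(window) == 1)
  if (nchar(window) == 0) rlang::abort("empty window")
  window <- toupper(window)
  L <- nchar(window)
  n_c <- stringr::str_count(window, stringr::fixed("C"))
  n_g <- stringr::str_count(window, stringr::fixed("G"))
  if (n_c == 0 || n_g == 0) return(0)
  # overlapping CG matches cannot occur (CG cannot overlap itself)
  n_cg <- stringr::str_count(window, stringr::fixed("CG"))
  n_cg * L / (n_c * n_g)
}

#' GC fraction of a DNA string
#'
#' @param window A single DNA string. `N` bases count toward the length only.
#' @return GC content as a fraction in \[0, 1\].
#' @export
gc_fraction <- function(window) {
  stopifnot(is.character(window), length(window) == 1)
  if (nchar(window) == 0) rlang::abort("empty window")
  window <- toupper(window)
  (stringr::str_count(window, stringr::fixed("C")) +
     stringr::str_count(window, stringr::fixed("G"))) / nchar(window)
}

# Sliding-window CpG statistics via cumulative sums: one row per window
# start (1-based), columns cpg_ratio and gc. Dinucleotides are counted only
# when fully inside the window.
window_stats <- function(sequence, window = 500L, step = 1L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < window) rlang::abort("sequence shorter than the scan window")
  is_c <- chars == "C"
  is_g <- chars == "G"
  is_cg <- c(is_c[-L] & is_g[-1], FALSE)
  cum_c <- c(0, cumsum(is_c))
  cum_g <- c(0, cumsum(is_g))
  cum_cg <- c(0, cumsum(is_cg))
  starts <- seq.int(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  n_c <- cum_c[ends + 1L] - cum_c[starts]
  n_g <- cum_g[ends + 1L] - cum_g[starts]
  n_cg <- cum_cg[ends] - cum_cg[starts]  # CG starting in [start, end - 1]
  ratio <- ifelse(n_c > 0 & n_g > 0, n_cg * window / (n_c * n_g), 0)
  gc <- (n_c + n_g) / window
  tibble::tibble(start = starts, cpg_ratio = ratio, gc = gc)
}

#' Classify a promoter sequence as HCP, ICP or LCP
#'
#' Scans every `window`-bp subsequence (step `step` bp) of the promoter and
#' applies CpG-density rules: the promoter is an HCP (high-CpG promoter) if at
#' least one window has CpG ratio strictly above `hcp_ratio` *and* GC content
#' strictly above `hcp_gc`; an LCP (low-CpG promoter) if no window has CpG
#' ratio above `lcp_ratio`; and an ICP (intermediate) otherwise. The three
#' classes partition all inputs. The sequence supplied should be the
#' forward-strand reference sequence of the promoter interval; the CpG
#' dinucleotide is strand-symmetric, so no reverse-complement pass is needed.
#'
#' @param sequence A single DNA string of length `>= window`.
#' @param window Scan window in bp (default 500).
#' @param hcp_ratio,hcp_gc,lcp_ratio Class thresholds (defaults 0.75, 0.55,
#'   0.48); all comparisons are strict.
#' @param step Window step in bp. The default 1 scans exhaustively, the
#'   faithful reading of "contains at least one 500-bp region"; larger steps
#'   trade a little sensitivity for speed.
#'
#' @return A one-row tibble: `cls` (factor HCP/ICP/LCP),
#'   `best_window_cpg_ratio` and `best_window_gc` (stats of the window with
#'   the highest CpG ratio, ties broken by GC).
#' @seealso [classify_promoters()] for whole tables, [cpg_ratio()].
#' @export
classify_promoter <- function(sequence, window = 500L, hcp_ratio = 0.75,
                              hcp_gc = 0.55, lcp_ratio = 0.48, step = 1L) {
  ws <- window_stats(sequence, window = window, step = step)
  best <- ws[order(-ws$cpg_ratio, -ws$gc), ][1, ]
  cls <- if (any(ws$cpg_ratio > hcp_ratio & ws$gc > hcp_gc)) {
    "HCP"
  } else if (!any(ws$cpg_ratio > lcp_ratio)) {
    "LCP"
  } else {
    "ICP"
  }
  tibble::tibble(
    cls = factor(cls, levels = c("HCP", "ICP", "LCP")),
    best_window_cpg_ratio = best$cpg_ratio,
    best_window_gc = best$gc
  )
}

#' Classify all promoters in a table
#'
#' Applies [classify_promoter()] to each row of a promoter table. Promoters
#' with a missing sequence are dropped with a warning (they cannot be
#' classified); duplicate gene ids are an error.
#'
#' @param promoters A data frame with columns `gene_id`, `sequence`, and
#'   optionally `biotype` (carried through).
#' @inheritParams classify_promoter
#' @return A tibble with `gene_id`, (`biotype`,) `cls`,
#'   `best_window_cpg_ratio`, `best_window_gc`.
#' @export
classify_promoters <- function(promoters, window = 500L, hcp_ratio = 0.75,
                               hcp_gc = 0.55, lcp_ratio = 0.48, step = 1L) {
  stopifnot(is.data.frame(promoters))
  if (nrow(promoters) == 0) {
    return(tibble::tibble(
      gene_id = character(),
      cls = factor(character(), levels = c("HCP", "ICP", "LCP")),
      best_window_cpg_ratio = numeric(), best_window_gc = numeric()
    ))
  }
  if (!all(c("gene_id", "sequence") %in% names(promoters))) {
    rlang::abort("promoters needs columns gene_id and sequence")
  }
  if (anyDuplicated(promoters$gene_id)) {
    rlang::abort("duplicate gene_id in promoters")
  }
  missing_seq <- is.na(promoters$sequence) | promoters$sequence == ""
  if (any(missing_seq)) {
    rlang::warn(sprintf("%d promoter(s) without sequence excluded from classification",
                        sum(missing_seq)))
    promoters <- promoters[!missing_seq, ]
  }
  res <- purrr::map(promoters$sequence, classify_promoter, window = window,
                    hcp_ratio = hcp_ratio, hcp_gc = hcp_gc,
                    lcp_ratio = lcp_ratio, step = step) |>
    purrr::list_rbind()
  keep <- intersect(c("gene_id", "biotype"), names(promoters))
  dplyr::bind_cols(tibble::as_tibble(promoters[keep]), res)
}

#' Summarise promoter classes by biotype
#'
#' @param classes Output of [classify_promoters()] (must carry `biotype`).
#' @return A tibble with one row per `biotype` x `cls` combination (zeros
#'   included) and a count `n`.
#' @export
class_summary <- function(classes) {
  stopifnot(all(c("biotype", "cls") %in% names(classes)))
  classes |>
    dplyr::count(.data$biotype, .data$cls, .drop = FALSE) |>
    tibble::as_tibble()
}
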