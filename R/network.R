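#' Pearson correlation with a t-distribution p-value
#'
#' Pearson r between two sample vectors (pairwise-complete) and the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom; `r = +/-1` gives `p = 0` by convention.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   are dropped, and at least 3 complete pairs are required.
#' @return A one-row tibble: `r`, `p`, `n` (complete pairs used). Zero
#'   variance in either vector yields `r = NA` (the pair cannot be tested).
#' @export
correlation_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) rlang::abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2)
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Build the candidate lncRNA-mRNA co-expression network
#'
#' Tests every candidate lncRNA x candidate mRNA pair on the shared
#' expression samples and retains edges with correlation strictly above
#' `r_cut` and p strictly below `p_cut` (signed r by default: positive
#' co-expression only; set `absolute = TRUE` for |r|). The result is a
#' bipartite graph summarised by node degrees. With 6 samples, r > 0.98
#' corresponds to p of about 6e-4, so the correlation threshold dominates
#' the joint filter.
#'
#' @param expr_mrna,expr_lncrna Matrix tibbles of (normalized) expression on
#'   the same samples.
#' @param candidates Candidate markers ([integrate_markers()] output, or any
#'   data frame with a `feature_id` column; a `biotype` column restricts
#'   each side). An empty candidate set yields an empty network.
#' @param r_cut,p_cut Edge thresholds (defaults 0.98 and 0.01, both strict).
#' @param absolute Threshold |r| instead of signed r (default `FALSE`).
#' @return An object of class `coexpression_network`: list with `edges`
#'   (tibble: `lncrna_id`, `mrna_id`, `r`, `p`, `n`), `degrees` (tibble:
#'   `node`, `type`, `degree`), `n_nodes`, `n_edges`, and the thresholds.
#'   Nodes are the candidates on each side; zero-variance features are
#'   skipped with a message.
#' @export
build_network <- function(expr_mrna, expr_lncrna, candidates,
                          r_cut = 0.98, p_cut = 0.01, absolute = FALSE) {
  m_m <- mat_from_tbl(expr_mrna)
  m_l <- mat_from_tbl(expr_lncrna)
  shared <- intersect(colnames(m_m), colnames(m_l))
  if (length(shared) < 3) rlang::abort("need >= 3 shared samples")
  m_m <- m_m[, shared, drop = FALSE]
  m_l <- m_l[, shared, drop = FALSE]

  ids <- unique(candidates$feature_id)
  if ("biotype" %in% names(candidates)) {
    cand_m <- intersect(candidates$feature_id[candidates$biotype == "mRNA"],
                        rownames(m_m))
    cand_l <- intersect(candidates$feature_id[candidates$biotype == "lncRNA"],
                        rownames(m_l))
  } else {
    cand_m <- intersect(ids, rownames(m_m))
    cand_l <- intersect(ids, rownames(m_l))
  }

  edges <- tibble::tibble(lncrna_id = character(), mrna_id = character(),
                          r = numeric(), p = numeric(), n = integer())
  if (length(cand_m) > 0 && length(cand_l) > 0) {
    a_l <- m_l[cand_l, , drop = FALSE]
    a_m <- m_m[cand_m, , drop = FALSE]
    sd_l <- apply(a_l, 1, sd)
    sd_m <- apply(a_m, 1, sd)
    if (any(sd_l == 0) || any(sd_m == 0)) {
      rlang::inform(sprintf(
        "%d zero-variance candidate(s) skipped",
        sum(sd_l == 0) + sum(sd_m == 0)))
      a_l <- a_l[sd_l > 0, , drop = FALSE]
      a_m <- a_m[sd_m > 0, , drop = FALSE]
    }
    if (nrow(a_l) > 0 && nrow(a_m) > 0) {
      n <- length(shared)
      rmat <- cor(t(a_l), t(a_m))  # lnc x mrna
      stat <- if (absolute) abs(rmat) else rmat
      pmat <- ifelse(abs(rmat) >= 1, 0,
                     2 * pt(-abs(rmat) * sqrt((n - 2) / (1 - rmat^2)),
                            df = n - 2))
      keep <- which(stat > r_cut & pmat < p_cut, arr.ind = TRUE)
      if (nrow(keep) > 0) {
        edges <- tibble::tibble(
          lncrna_id = rownames(rmat)[keep[, 1]],
          mrna_id = colnames(rmat)[keep[, 2]],
          r = rmat[keep], p = pmat[keep], n = n
        ) |>
          dplyr::arrange(.data$lncrna_id, .data$mrna_id)
      }
    }
  }
  degrees <- dplyr::bind_rows(
    tibble::tibble(node = cand_l, type = "lncRNA"),
    tibble::tibble(node = cand_m, type = "mRNA")
  ) |>
    dplyr::left_join(
      dplyr::count(
        tidyr::pivot_longer(edges[c("lncrna_id", "mrna_id")],
                            dplyr::everything(), values_to = "node"),
        .data$node, name = "degree"),
      by = "node") |>
    dplyr::mutate(degree = tidyr::replace_na(.data$degree, 0L))
  structure(list(
    edges = edges, degrees = degrees,
    n_nodes = nrow(degrees), n_edges = nrow(edges),
    r_cut = r_cut, p_cut = p_cut, absolute = absolute
  ), class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "<coexpression_network> %d nodes, %d edges (r > %g, p < %g%s)\n",
    x$n_nodes, x$n_edges, x$r_cut, x$p_cut,
    if (x$absolute) ", |r|" else ""))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' @param network A `coexpression_network` from [build_network()].
#' @param top_k Number of top nodes to return (positive).
#' @return A tibble `node`, `type`, `degree`, sorted by degree descending
#'   with ties broken by node id; at most `top_k` rows.
#' @export
rank_hubs <- function(network, top_k = 10L) {
  stopifnot(inherits(network, "coexpression_network"))
  if (top_k <= 0) rlang::abort("top_k must be positive")
  network$degrees |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node) |>
    dplyr::slice_head(n = top_k)
}

#' Export a network as a Cytoscape SIF file
#'
#' Writes one line per edge: `lncrna_id coexp mrna_id`, tab-separated.
#'
#' @param network A `coexpression_network`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sif <- function(network, file) {
  stopifnot(inherits(network, "coexpression_network"))
  lines <- sprintf("%s\tcoexp\t%s",
                   network$edges$lncrna_id, network$edges$mrna_id)
  writeLines(lines, file)
  invisible(file)
}
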