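#' Configuration for the synthetic paired cohort generator
#'
#' Bundles every knob of the synthetic expression + methylation cohort:
#' cohort sizes, promoter geometry, CpG-class mix, planted effect sizes and
#' noise scales. Defaults emulate the study design the package targets: a
#' 3 vs 3 expression cohort and a 3 control vs 8 disease methylation cohort,
#' 2-kb promoters, bounded beta-value noise, and log2-scale array-like
#' intensities with planted fold changes anti-correlated with planted
#' promoter methylation shifts.
#'
#' Planted genes are drawn from ICP promoters (baseline beta near 0.5) so a
#' +/- `beta_shift_effect` stays well inside (0, 1); `n_planted_up_hypo` and
#' `n_planted_down_hyper` are per-biotype counts. Planted co-expression edges
#' pair the i-th planted lncRNA with the i-th planted mRNA of the same
#' direction; the lncRNA profile is the partner's profile plus independent
#' noise of sd `edge_noise_sd`, which pins their sample correlation near 1.
#' `coexpr_latent_sd > 0` additionally injects a per-pair shared latent
#' factor, useful for studying the edge filter with no group effect planted
#' (`expr_log2fc_effect = 0`).
#'
#' @param n_genes_mrna,n_genes_lncrna Number of mRNA / lncRNA genes.
#' @param n_samples_ctrl_expr,n_samples_uc_expr Expression cohort sizes
#'   (defaults 3 and 3).
#' @param n_samples_ctrl_meth,n_samples_uc_meth Methylation cohort sizes
#'   (defaults 3 and 8).
#' @param promoter_len Promoter length in bp (default 2000; one quarter lies
#'   downstream of the TSS).
#' @param frac_hcp,frac_icp,frac_lcp Promoter class mix; must sum to 1.
#' @param n_planted_up_hypo,n_planted_down_hyper Planted genes per biotype:
#'   up-regulated with hypo-methylated promoter, and down-regulated with
#'   hyper-methylated promoter.
#' @param expr_log2fc_effect Planted |log2 fold change| (default 2).
#' @param beta_shift_effect Planted promoter mean-beta shift in (0, 1)
#'   (default 0.3).
#' @param beta_concentration Beta-distribution concentration (shape1 + shape2)
#'   of site-level noise; larger is tighter (default 50).
#' @param expr_sd Within-group log2 intensity sd (default 0.15).
#' @param n_planted_edges Number of planted lncRNA-mRNA co-expression pairs;
#'   defaults to all same-direction planted pairs.
#' @param edge_noise_sd Independent noise added to a planted edge's lncRNA
#'   copy of its partner profile (default 0.05, log2 units).
#' @param coexpr_latent_sd Sd of the per-edge shared latent factor (default
#'   0: the planted group effect alone carries the pair correlation).
#' @param seed Root seed; every stage derives its own RNG stream from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_genes_mrna = 140L, n_genes_lncrna = 100L,
                       n_samples_ctrl_expr = 3L, n_samples_uc_expr = 3L,
                       n_samples_ctrl_meth = 3L, n_samples_uc_meth = 8L,
                       promoter_len = 2000L,
                       frac_hcp = 0.10, frac_icp = 0.25, frac_lcp = 0.65,
                       n_planted_up_hypo = 4L, n_planted_down_hyper = 3L,
                       expr_log2fc_effect = 2.0, beta_shift_effect = 0.3,
                       beta_concentration = 50, expr_sd = 0.15,
                       n_planted_edges = NULL, edge_noise_sd = 0.05,
                       coexpr_latent_sd = 0, seed = 1L) {
  cfg <- list(
    n_genes_mrna = as.integer(n_genes_mrna),
    n_genes_lncrna = as.integer(n_genes_lncrna),
    n_samples_ctrl_expr = as.integer(n_samples_ctrl_expr),
    n_samples_uc_expr = as.integer(n_samples_uc_expr),
    n_samples_ctrl_meth = as.integer(n_samples_ctrl_meth),
    n_samples_uc_meth = as.integer(n_samples_uc_meth),
    promoter_len = as.integer(promoter_len),
    frac_hcp = frac_hcp, frac_icp = frac_icp, frac_lcp = frac_lcp,
    n_planted_up_hypo = as.integer(n_planted_up_hypo),
    n_planted_down_hyper = as.integer(n_planted_down_hyper),
    expr_log2fc_effect = expr_log2fc_effect,
    beta_shift_effect = beta_shift_effect,
    beta_concentration = beta_concentration,
    expr_sd = expr_sd,
    n_planted_edges = if (is.null(n_planted_edges)) NULL else as.integer(n_planted_edges),
    edge_noise_sd = edge_noise_sd,
    coexpr_latent_sd = coexpr_latent_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genes_mrna", "n_genes_lncrna", "n_samples_ctrl_expr",
              "n_samples_uc_expr", "n_samples_ctrl_meth", "n_samples_uc_meth",
              "promoter_len")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      rlang::abort(sprintf("sim_config: %s must be a positive integer", f))
    }
  }
  if (cfg$promoter_len < 1000) {
    rlang::abort("sim_config: promoter_len must be >= 1000 bp")
  }
  fr <- cfg$frac_hcp + cfg$frac_icp + cfg$frac_lcp
  if (abs(fr - 1) > 1e-9) {
    rlang::abort("sim_config: frac_hcp + frac_icp + frac_lcp must sum to 1")
  }
  if (any(c(cfg$frac_hcp, cfg$frac_icp, cfg$frac_lcp) < 0)) {
    rlang::abort("sim_config: class fractions must be non-negative")
  }
  if (cfg$n_planted_up_hypo < 0 || cfg$n_planted_down_hyper < 0) {
    rlang::abort("sim_config: planted counts must be non-negative")
  }
  if (cfg$beta_shift_effect <= 0 || cfg$beta_shift_effect >= 1) {
    rlang::abort("sim_config: beta_shift_effect must lie in (0, 1)")
  }
  if (cfg$beta_concentration <= 0 || cfg$expr_sd <= 0) {
    rlang::abort("sim_config: beta_concentration and expr_sd must be positive")
  }
  invisible(cfg)
}

# Largest-remainder allocation of n items to fractions summing to 1.
alloc_counts <- function(n, fracs) {
  base <- floor(n * fracs)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * fracs - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate gene models with planted truth
#'
#' Lays out mRNA and lncRNA gene models on a single synthetic chromosome so
#' that their 2-kb promoters are non-overlapping (>= 1 kb gaps), alternating
#' strands. Each gene is assigned a target promoter class (HCP/ICP/LCP) by
#' the configured mix, and planted differential genes (up-regulated with
#' hypo-methylated promoter; down-regulated with hyper-methylated promoter)
#' are drawn from the ICP genes of each biotype, then paired same-direction
#' across biotypes into planted co-expression edges.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `biotype`), `truth` (list: `planted_up_hypo`,
#'   `planted_down_hyper`, `planted_edges` tibble, `promoter_class_by_gene`
#'   tibble), and `chrom_len`.
#' @export
simulate_genes <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 11L))
  n_m <- config$n_genes_mrna
  n_l <- config$n_genes_lncrna
  n <- n_m + n_l
  up <- config$promoter_len - config$promoter_len %/% 4L  # upstream extent
  dn <- config$promoter_len %/% 4L
  gap <- 1000L
  prom_start <- gap + (seq_len(n) - 1L) * (config$promoter_len + gap)
  strand <- rep_len(c("+", "-"), n)
  tss <- ifelse(strand == "+", prom_start + up, prom_start + dn)
  body_len <- 400L
  gene_start <- ifelse(strand == "+", tss, tss - body_len + 1L)
  gene_end <- ifelse(strand == "+", tss + body_len, tss + 1L)
  biotype <- c(rep("mRNA", n_m), rep("lncRNA", n_l))
  gene_id <- c(sprintf("MRNA%04d", seq_len(n_m)),
               sprintf("LNC%04d", seq_len(n_l)))
  genes <- tibble::tibble(
    gene_id = gene_id, chrom = "chrS",
    start = as.integer(gene_start), end = as.integer(gene_end),
    strand = strand, tss = as.integer(tss), biotype = biotype
  )
  chrom_len <- max(prom_start) + config$promoter_len + gap

  fracs <- c(HCP = config$frac_hcp, ICP = config$frac_icp, LCP = config$frac_lcp)
  cls <- character(n)
  planted_up <- character(0)
  planted_down <- character(0)
  n_planted <- config$n_planted_up_hypo + config$n_planted_down_hyper
  for (bt in c("mRNA", "lncRNA")) {
    idx <- which(biotype == bt)
    counts <- alloc_counts(length(idx), fracs)
    if (n_planted > 0 && counts[2] < n_planted) {
      rlang::abort(sprintf(
        "sizing error: %d ICP %s genes available but %d planted genes requested",
        counts[2], bt, n_planted))
    }
    labels <- sample(rep(names(fracs), times = counts))
    cls[idx] <- labels
    icp_ids <- gene_id[idx][labels == "ICP"]
    picked <- sample(icp_ids, n_planted)
    planted_up <- c(planted_up, picked[seq_len(config$n_planted_up_hypo)])
    planted_down <- c(planted_down,
                      picked[config$n_planted_up_hypo + seq_len(config$n_planted_down_hyper)])
  }

  pair_dir <- function(ids_l, ids_m, direction) {
    k <- min(length(ids_l), length(ids_m))
    if (k == 0) return(NULL)
    tibble::tibble(lncrna_id = ids_l[seq_len(k)], mrna_id = ids_m[seq_len(k)],
                   direction = direction)
  }
  is_l <- function(x) startsWith(x, "LNC")
  edges <- dplyr::bind_rows(
    pair_dir(planted_up[is_l(planted_up)], planted_up[!is_l(planted_up)], "up"),
    pair_dir(planted_down[is_l(planted_down)], planted_down[!is_l(planted_down)], "down")
  )
  if (is.null(edges)) {
    edges <- tibble::tibble(lncrna_id = character(), mrna_id = character(),
                            direction = character())
  }
  n_edges <- config$n_planted_edges %||% nrow(edges)
  if (n_edges > nrow(edges)) {
    rlang::abort(sprintf(
      "sizing error: %d planted edges requested but only %d same-direction planted pairs exist",
      n_edges, nrow(edges)))
  }
  edges <- edges[seq_len(n_edges), ]

  truth <- list(
    planted_up_hypo = planted_up,
    planted_down_hyper = planted_down,
    planted_edges = edges,
    promoter_class_by_gene = tibble::tibble(
      gene_id = gene_id, biotype = biotype,
      cls = factor(cls, levels = c("HCP", "ICP", "LCP"))
    )
  )
  list(genes = genes, truth = truth, chrom_len = chrom_len)
}

# Token-emission sequence builders. Each emits ~`len` bases; `p_cg` is the
# probability of emitting a CpG dinucleotide token, `p_single` the base
# distribution of single-base tokens (A, C, G, T).
emit_tokens <- function(len, p_cg, p_single) {
  n_tok <- len  # upper bound; each token adds >= 1 base
  tok <- runif(n_tok) < p_cg
  singles <- sample(c("A", "C", "G", "T"), n_tok, replace = TRUE,
                    prob = p_single)
  pieces <- ifelse(tok, "CG", singles)
  s <- paste(pieces, collapse = "")
  substr(s, 1L, len)
}

#' Simulate a promoter sequence of a requested CpG class
#'
#' Generates a random DNA sequence whose [classify_promoter()] class equals
#' `target_class`, by a class-specific compositional generator followed by a
#' classify-and-resample check. HCP sequences are CpG-island-like throughout
#' (high GC, frequent CpG); LCP sequences are CpG-depleted and AT-rich; ICP
#' sequences carry a single moderate 500-bp CpG-enriched island on a
#' CpG-poor background. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param target_class `"HCP"`, `"ICP"` or `"LCP"`.
#' @param length Sequence length in bp, at least 500.
#' @param max_attempts Resampling budget before giving up (default 50).
#' @return A DNA string of the requested length and class.
#' @export
simulate_promoter_sequence <- function(target_class = c("HCP", "ICP", "LCP"),
                                       length = 2000L, max_attempts = 50L) {
  target_class <- match.arg(target_class)
  if (length < 500L) rlang::abort("promoter sequence length must be >= 500 bp")
  gen <- switch(target_class,
    HCP = function() emit_tokens(length, 0.12, c(0.20, 0.30, 0.30, 0.20)),
    LCP = function() {
      s <- emit_tokens(length, 0, c(0.33, 0.17, 0.17, 0.33))
      # deplete CpGs to ~10% of their random-composition rate, keeping a few
      # so LCP promoters still carry measurable methylation sites
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      cg <- which(chars[-length(chars)] == "C" & chars[-1] == "G")
      drop <- cg[runif(length(cg)) < 0.9]
      chars[drop + 1L] <- "A"
      paste(chars, collapse = "")
    },
    ICP = function() {
      bg_l <- (length - 500L) %/% 2L
      bg_r <- length - 500L - bg_l
      bg <- function(k) {
        if (k == 0) return("")
        gsub("CG", "CT", emit_tokens(k, 0, c(0.30, 0.20, 0.20, 0.30)),
             fixed = TRUE)
      }
      island <- emit_tokens(500L, 0.04, c(0.27, 0.23, 0.23, 0.27))
      paste0(bg(bg_l), island, bg(bg_r))
    }
  )
  for (i in seq_len(max_attempts)) {
    s <- gen()
    if (nchar(s) == length &&
        as.character(classify_promoter(s)$cls) == target_class) {
      return(s)
    }
  }
  rlang::abort(sprintf("could not generate a %s promoter in %d attempts",
                       target_class, max_attempts))
}

#' Simulate CpG-site methylation for a set of promoters
#'
#' CpG sites are the CG dinucleotide positions of each promoter sequence.
#' Site-level beta values are drawn from a Beta distribution parameterised by
#' a promoter-level mean and a concentration: control means sit at
#' class-typical baselines (HCP lowest, ICP intermediate, LCP highest, with
#' small per-gene jitter), and planted promoters are shifted by
#' +/- `beta_shift_effect` in the disease group (hyper-methylated for planted
#' down-regulated genes, hypo-methylated for planted up-regulated genes).
#' All values lie in (0, 1).
#'
#' @param promoters Promoter table with `gene_id`, `chrom`, `start` and
#'   `sequence` columns (see [simulate_cohort()]).
#' @param truth Truth object from [simulate_genes()].
#' @param config A [sim_config()].
#' @return A list with `beta` (matrix tibble: `site_id` x methylation
#'   samples), `sites` (manifest tibble: `site_id`, `chrom`, `pos`, 0-based),
#'   and `samples` (tibble: `sample_id`, `group`, `assay`).
#' @export
simulate_methylation <- function(promoters, truth, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 23L))
  baselines <- c(HCP = 0.15, ICP = 0.50, LCP = 0.80)
  cls_by_gene <- setNames(as.character(truth$promoter_class_by_gene$cls),
                          truth$promoter_class_by_gene$gene_id)
  planted <- c(truth$planted_up_hypo, truth$planted_down_hyper)

  n_ctrl <- config$n_samples_ctrl_meth
  n_uc <- config$n_samples_uc_meth
  samples <- tibble::tibble(
    sample_id = c(sprintf("m_ctrl_%d", seq_len(n_ctrl)),
                  sprintf("m_uc_%d", seq_len(n_uc))),
    group = c(rep("ctrl", n_ctrl), rep("uc", n_uc)),
    assay = "meth"
  )

  site_rows <- vector("list", nrow(promoters))
  beta_rows <- vector("list", nrow(promoters))
  site_counter <- 0L
  for (i in seq_len(nrow(promoters))) {
    g <- promoters$gene_id[i]
    seq_i <- promoters$sequence[i]
    offs <- as.integer(gregexpr("CG", seq_i, fixed = TRUE)[[1]])
    offs <- offs[offs > 0]
    if (length(offs) == 0) {
      if (g %in% planted) {
        rlang::abort(sprintf(
          "generation error: planted gene %s has a promoter with zero CpG sites", g))
      }
      next
    }
    n_sites <- length(offs)
    ids <- sprintf("cg%06d", site_counter + seq_len(n_sites))
    site_counter <- site_counter + n_sites
    site_rows[[i]] <- tibble::tibble(
      site_id = ids, chrom = promoters$chrom[i],
      pos = as.integer(promoters$start[i] + offs - 1L)
    )
    base <- baselines[[cls_by_gene[[g]]]]
    m_ctrl <- min(max(base + rnorm(1, 0, 0.02), 0.05), 0.95)
    shift <- if (g %in% truth$planted_down_hyper) {
      config$beta_shift_effect
    } else if (g %in% truth$planted_up_hypo) {
      -config$beta_shift_effect
    } else {
      0
    }
    m_uc <- min(max(m_ctrl + shift, 0.02), 0.98)
    conc <- config$beta_concentration
    draw <- function(m, k) rbeta(k, m * conc, (1 - m) * conc)
    vals <- cbind(
      matrix(draw(m_ctrl, n_sites * n_ctrl), nrow = n_sites),
      matrix(draw(m_uc, n_sites * n_uc), nrow = n_sites)
    )
    colnames(vals) <- samples$sample_id
    beta_rows[[i]] <- dplyr::bind_cols(tibble::tibble(site_id = ids),
                                       tibble::as_tibble(vals))
  }
  list(
    beta = dplyr::bind_rows(beta_rows),
    sites = dplyr::bind_rows(site_rows),
    samples = samples
  )
}

#' Simulate mRNA and lncRNA expression matrices
#'
#' Log2-scale intensities with gene baselines uniform on \[6, 12\], Gaussian
#' within-group noise of sd `expr_sd`, and a planted group effect of
#' +/- `expr_log2fc_effect` for planted genes (up for hypo-methylated,
#' down for hyper-methylated, matching the concordance the integration stage
#' looks for). Each planted co-expression edge copies the partner mRNA's
#' profile into the lncRNA (re-centred at the lncRNA's own baseline) plus
#' independent noise of sd `edge_noise_sd`, optionally on top of a shared
#' latent factor of sd `coexpr_latent_sd` added to the mRNA.
#'
#' @inheritParams simulate_methylation
#' @param genes Gene table from [simulate_genes()].
#' @return A list with `mrna` and `lncrna` matrix tibbles (`gene_id` x
#'   expression samples) and `samples` (tibble: `sample_id`, `group`,
#'   `assay`).
#' @export
simulate_expression <- function(genes, truth, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 37L))
  n_ctrl <- config$n_samples_ctrl_expr
  n_uc <- config$n_samples_uc_expr
  n_s <- n_ctrl + n_uc
  samples <- tibble::tibble(
    sample_id = c(sprintf("e_ctrl_%d", seq_len(n_ctrl)),
                  sprintf("e_uc_%d", seq_len(n_uc))),
    group = c(rep("ctrl", n_ctrl), rep("uc", n_uc)),
    assay = "expr"
  )
  is_uc <- samples$group == "uc"
  mu <- runif(nrow(genes), 6, 12)
  names(mu) <- genes$gene_id
  effect <- numeric(nrow(genes))
  names(effect) <- genes$gene_id
  effect[genes$gene_id %in% truth$planted_up_hypo] <- config$expr_log2fc_effect
  effect[genes$gene_id %in% truth$planted_down_hyper] <- -config$expr_log2fc_effect

  vals <- matrix(rnorm(nrow(genes) * n_s, sd = config$expr_sd),
                 nrow = nrow(genes), dimnames = list(genes$gene_id, samples$sample_id))
  vals <- vals + mu + outer(effect, as.numeric(is_uc))

  edges <- truth$planted_edges
  if (nrow(edges) > 0) {
    if (config$coexpr_latent_sd > 0) {
      for (j in seq_len(nrow(edges))) {
        f <- rnorm(n_s, 0, config$coexpr_latent_sd)
        vals[edges$mrna_id[j], ] <- vals[edges$mrna_id[j], ] + f
      }
    }
    for (j in seq_len(nrow(edges))) {
      m_id <- edges$mrna_id[j]
      l_id <- edges$lncrna_id[j]
      vals[l_id, ] <- vals[m_id, ] - mu[[m_id]] + mu[[l_id]] +
        rnorm(n_s, 0, config$edge_noise_sd)
    }
  }

  split_bt <- function(bt) {
    ids <- genes$gene_id[genes$biotype == bt]
    tbl_from_mat(vals[ids, , drop = FALSE], "gene_id")
  }
  list(mrna = split_bt("mRNA"), lncrna = split_bt("lncRNA"), samples = samples)
}

#' Simulate a full paired expression + methylation cohort
#'
#' Runs the whole generator: gene layout with planted truth, class-targeted
#' promoter sequences, CpG-site methylation, and expression matrices. Every
#' stage seeds its own RNG stream from the root `config$seed`, so the result
#' is fully deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `methex_sim`: `config`, `genes`, `promoters`
#'   (with `sequence`), `sites`, `beta`, `expr_mrna`, `expr_lncrna`,
#'   `samples` (both assays), `truth`, `chrom_len`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_genes_mrna = 30, n_genes_lncrna = 20,
#'                                   seed = 7))
#' dplyr::count(sim$truth$promoter_class_by_gene, biotype, cls)
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  gt <- simulate_genes(config)
  up <- config$promoter_len - config$promoter_len %/% 4L
  dn <- config$promoter_len %/% 4L
  promoters <- derive_promoters(gt$genes, chrom_len = gt$chrom_len,
                                upstream = up, downstream = dn)
  set.seed(derive_seed(config$seed, 17L))
  cls <- setNames(as.character(gt$truth$promoter_class_by_gene$cls),
                  gt$truth$promoter_class_by_gene$gene_id)
  promoters$sequence <- vapply(
    promoters$gene_id,
    function(g) simulate_promoter_sequence(cls[[g]], config$promoter_len),
    character(1)
  )
  meth <- simulate_methylation(promoters, gt$truth, config)
  expr <- simulate_expression(gt$genes, gt$truth, config)
  structure(list(
    config = config,
    genes = gt$genes,
    promoters = promoters,
    sites = meth$sites,
    beta = meth$beta,
    expr_mrna = expr$mrna,
    expr_lncrna = expr$lncrna,
    samples = dplyr::bind_rows(expr$samples, meth$samples),
    truth = gt$truth,
    chrom_len = gt$chrom_len
  ), class = "methex_sim")
}

#' @export
print.methex_sim <- function(x, ...) {
  cat("<methex_sim> synthetic paired cohort\n")
  cat(sprintf("  genes: %d mRNA + %d lncRNA on %s (len %d)\n",
              x$config$n_genes_mrna, x$config$n_genes_lncrna,
              x$genes$chrom[1], x$chrom_len))
  cat(sprintf("  CpG sites: %d; samples: %d expr + %d meth\n",
              nrow(x$sites), sum(x$samples$assay == "expr"),
              sum(x$samples$assay == "meth")))
  cat(sprintf("  planted: %d up/hypo, %d down/hyper, %d edges\n",
              length(x$truth$planted_up_hypo),
              length(x$truth$planted_down_hyper),
              nrow(x$truth$planted_edges)))
  invisible(x)
}
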