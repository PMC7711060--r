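test_that("gene layout honours the config: counts, strands, spacing", {
  cfg <- sim_config(n_genes_mrna = 30, n_genes_lncrna = 20,
                    n_planted_up_hypo = 2, n_planted_down_hyper = 1, seed = 1)
  gt <- simulate_genes(cfg)
  expect_equal(nrow(gt$genes), 50)
  expect_equal(nrow(gt$truth$promoter_class_by_gene), 50)
  expect_setequal(unique(gt$genes$strand), c("+", "-"))
  # promoters non-overlapping with >= 1 kb gaps
  p <- derive_promoters(gt$genes, chrom_len = gt$chrom_len)
  p <- p[order(p$start), ]
  expect_true(all(diff(p$start) - 2000 >= 1000))
  # planted sets disjoint, all genes exist
  tr <- gt$truth
  expect_length(intersect(tr$planted_up_hypo, tr$planted_down_hyper), 0)
  expect_true(all(c(tr$planted_up_hypo, tr$planted_down_hyper,
                    tr$planted_edges$lncrna_id, tr$planted_edges$mrna_id)
                  %in% gt$genes$gene_id))
})

test_that("the same config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_genes_mrna = 25, n_genes_lncrna = 25,
                    n_planted_up_hypo = 1, n_planted_down_hyper = 1, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$promoters$sequence, s2$promoters$sequence)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$expr_mrna, s2$expr_mrna)
  expect_identical(s1$truth, s2$truth)
})

test_that("target-class sequence generation always satisfies the classifier", {
  set.seed(5)
  for (cls in c("HCP", "ICP", "LCP")) {
    for (i in 1:10) {
      s <- simulate_promoter_sequence(cls, 2000)
      expect_equal(as.character(classify_promoter(s)$cls), cls)
    }
  }
})

test_that("methylation betas live in [0,1] with the planted group shifts", {
  sim <- shared_sim()
  m <- as.matrix(sim$beta[-1])
  expect_true(all(m >= 0 & m <= 1))
  map <- map_sites_to_promoters(sim$sites, sim$promoters, quiet = TRUE)
  pm <- promoter_methylation(sim$beta, map)
  mm <- as.matrix(pm[-1])
  rownames(mm) <- pm$gene_id
  ms <- meth_samples(sim)
  d <- rowMeans(mm[, ms$sample_id[ms$group == "uc"]]) -
    rowMeans(mm[, ms$sample_id[ms$group == "ctrl"]])
  tr <- sim$truth
  expect_true(all(abs(d[tr$planted_down_hyper] - 0.3) < 0.1))
  expect_true(all(abs(d[tr$planted_up_hypo] + 0.3) < 0.1))
  null_genes <- setdiff(names(d), c(tr$planted_down_hyper, tr$planted_up_hypo))
  expect_true(all(abs(d[null_genes]) < 0.1))
})

test_that("expression carries the planted fold changes and edge correlations", {
  sim <- shared_sim()
  em <- as.matrix(sim$expr_mrna[-1]); rownames(em) <- sim$expr_mrna$gene_id
  el <- as.matrix(sim$expr_lncrna[-1]); rownames(el) <- sim$expr_lncrna$gene_id
  es <- expr_samples(sim)
  uc <- es$sample_id[es$group == "uc"]
  ctrl <- es$sample_id[es$group == "ctrl"]
  lfc <- function(m) rowMeans(m[, uc]) - rowMeans(m[, ctrl])
  tr <- sim$truth
  up <- c(lfc(em), lfc(el))[tr$planted_up_hypo]
  down <- c(lfc(em), lfc(el))[tr$planted_down_hyper]
  expect_true(all(abs(up - 2) < 0.5))
  expect_true(all(abs(down + 2) < 0.5))
  for (i in seq_len(nrow(tr$planted_edges))) {
    r <- cor(el[tr$planted_edges$lncrna_id[i], ],
             em[tr$planted_edges$mrna_id[i], ])
    expect_gt(r, 0.98)
  }
})

test_that("fixtures round-trip through disk byte-for-byte and value-for-value", {
  cfg <- sim_config(n_genes_mrna = 25, n_genes_lncrna = 25,
                    n_planted_up_hypo = 1, n_planted_down_hyper = 1, seed = 5)
  sim <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(sim, d1)
  write_fixture(sim, d2)
  files <- c("genes.bed", "promoters.fa", "beta.tsv", "sites.tsv",
             "expr_mrna.tsv", "expr_lncrna.tsv", "samples.tsv", "truth.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  back <- read_fixture(d1)
  expect_equal(back$genes$gene_id, sim$genes$gene_id)
  expect_equal(back$genes$tss, sim$genes$tss)
  expect_equal(back$promoters$sequence, sim$promoters$sequence)
  expect_equal(back$beta, sim$beta)
  expect_equal(back$expr_mrna, sim$expr_mrna)
  expect_equal(as.data.frame(back$sites), as.data.frame(sim$sites))
  expect_identical(back$truth$planted_up_hypo, sim$truth$planted_up_hypo)
  expect_equal(back$truth$planted_edges, sim$truth$planted_edges)
  # referential integrity
  expect_true(all(c(back$truth$planted_up_hypo, back$truth$planted_down_hyper)
                  %in% back$genes$gene_id))
})

test_that("invalid configurations are rejected with sizing errors", {
  expect_error(sim_config(frac_hcp = 0.5, frac_icp = 0.5, frac_lcp = 0.5),
               "sum to 1")
  expect_error(sim_config(beta_shift_effect = 1.2), "beta_shift_effect")
  expect_error(sim_config(n_genes_mrna = 0), "positive")
  # too many planted genes for the ICP pool
  expect_error(
    simulate_genes(sim_config(n_genes_mrna = 20, n_genes_lncrna = 20,
                              n_planted_up_hypo = 10,
                              n_planted_down_hyper = 10)),
    "sizing error")
})
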