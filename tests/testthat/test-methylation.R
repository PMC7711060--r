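test_that("site assignment respects the half-open promoter interval", {
  promoters <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                              start = 100L, end = 200L)
  sites <- tibble::tibble(site_id = c("s_at_start", "s_inside", "s_at_end",
                                      "s_before", "s_other_chrom"),
                          chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                          pos = c(100L, 150L, 200L, 99L, 150L))
  map <- map_sites_to_promoters(sites, promoters, quiet = TRUE)
  expect_setequal(map$site_id, c("s_at_start", "s_inside"))
})

test_that("site assignment equals the brute-force double loop", {
  set.seed(3)
  promoters <- tibble::tibble(
    gene_id = paste0("g", 1:15),
    chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
    start = sample.int(5000, 15)
  ) |> dplyr::mutate(end = start + sample(c(200L, 500L, 1000L), 15,
                                          replace = TRUE))
  sites <- tibble::tibble(
    site_id = paste0("s", 1:200),
    chrom = sample(c("chr1", "chr2", "chr3"), 200, replace = TRUE),
    pos = sample.int(6000, 200)
  )
  got <- map_sites_to_promoters(sites, promoters, quiet = TRUE)
  want <- oracle_site_map(sites, promoters)
  expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  # a site overlapping two promoters is assigned to both
  two <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                        start = c(0L, 50L), end = c(100L, 150L))
  one <- tibble::tibble(site_id = "s", chrom = "chr1", pos = 75L)
  expect_equal(sort(map_sites_to_promoters(one, two, quiet = TRUE)$gene_id),
               c("a", "b"))
})

test_that("promoter methylation is the skip-missing mean over sites", {
  map <- tibble::tibble(gene_id = c("g1", "g2", "g2", "g2"),
                        site_id = c("s1", "s2", "s3", "s4"))
  beta <- tibble::tibble(site_id = paste0("s", 1:4),
                         a = c(0.7, 0.2, 0.4, 0.6),
                         b = c(0.5, 0.2, NA, 0.6),
                         c = c(0.1, NA, NA, NA))
  pm <- promoter_methylation(beta, map)
  expect_equal(pm$a[pm$gene_id == "g1"], 0.7)
  expect_equal(pm$a[pm$gene_id == "g2"], 0.4)
  expect_equal(pm$b[pm$gene_id == "g2"], 0.4)   # mean of 0.2 and 0.6
  expect_true(is.na(pm$c[pm$gene_id == "g2"]))  # all sites missing
})

test_that("DMP tails are exactly the extreme 5% by signed t", {
  set.seed(21)
  n <- 100
  m <- matrix(rbeta(n * 11, 5, 5), nrow = n,
              dimnames = list(sprintf("g%03d", 1:n),
                              c(paste0("c", 1:3), paste0("u", 1:8))))
  samples <- toy_samples(3, 8)
  pm <- tibble::as_tibble(m, rownames = "gene_id")
  dmp <- identify_dmps(pm, samples)
  expect_equal(sum(dmp$call == "hyper"), 5)
  expect_equal(sum(dmp$call == "hypo"), 5)
  # brute-force full sort oracle
  t_or <- sapply(rownames(m), function(g)
    unname(t.test(m[g, 4:11], m[g, 1:3], var.equal = TRUE)$statistic))
  expect_setequal(dmp$gene_id[dmp$call == "hyper"],
                  names(sort(t_or, decreasing = TRUE))[1:5])
  expect_setequal(dmp$gene_id[dmp$call == "hypo"],
                  names(sort(t_or))[1:5])
  expect_equal(dmp$t_stat[order(dmp$gene_id)],
               unname(t_or[order(names(t_or))]), tolerance = 1e-12)
  # every hyper t >= every uncalled t (and dually)
  expect_gte(min(dmp$t_stat[dmp$call == "hyper"]),
             max(dmp$t_stat[dmp$call == "none"]))
  expect_lte(max(dmp$t_stat[dmp$call == "hypo"]),
             min(dmp$t_stat[dmp$call == "none"]))
})

test_that("tail size uses round-half-up and label swap exchanges the tails", {
  set.seed(22)
  n <- 30  # 0.05 * 30 = 1.5 -> k = 2
  m <- matrix(rbeta(n * 6, 5, 5), nrow = n,
              dimnames = list(sprintf("g%02d", 1:n),
                              c(paste0("c", 1:3), paste0("u", 1:3))))
  pm <- tibble::as_tibble(m, rownames = "gene_id")
  samples <- toy_samples(3, 3)
  dmp <- identify_dmps(pm, samples)
  expect_equal(sum(dmp$call == "hyper"), 2)
  expect_equal(sum(dmp$call == "hypo"), 2)
  swapped <- identify_dmps(pm, samples, ref = "uc", case = "ctrl")
  expect_setequal(dmp$gene_id[dmp$call == "hyper"],
                  swapped$gene_id[swapped$call == "hypo"])
  expect_setequal(dmp$gene_id[dmp$call == "hypo"],
                  swapped$gene_id[swapped$call == "hyper"])
  # hyper calls raise methylation in the case group
  expect_true(all(dmp$delta_beta[dmp$call == "hyper"] > 0))
  expect_true(all(dmp$delta_beta[dmp$call == "hypo"] < 0))
})

test_that("per-biotype ranking calls tails within each stratum", {
  sim <- shared_sim()
  map <- map_sites_to_promoters(sim$sites, sim$promoters, quiet = TRUE)
  pm <- promoter_methylation(sim$beta, map)
  dmp <- identify_dmps(pm, meth_samples(sim), genes = sim$genes,
                       site_map = map)
  by_bt <- dplyr::count(dmp, biotype, call)
  k_m <- floor(0.05 * sum(dmp$biotype == "mRNA") + 0.5)
  k_l <- floor(0.05 * sum(dmp$biotype == "lncRNA") + 0.5)
  expect_equal(by_bt$n[by_bt$biotype == "mRNA" & by_bt$call == "hyper"], k_m)
  expect_equal(by_bt$n[by_bt$biotype == "lncRNA" & by_bt$call == "hypo"], k_l)
  expect_true(all(dmp$n_sites >= 1))
  expect_error(identify_dmps(pm, meth_samples(sim), tail_fraction = 0.6),
               "tail_fraction")
})

test_that("crosstab percentages recompute from their own counts", {
  # printed-report arithmetic at 2 decimals
  expect_equal(crosstab_pct(119, 6067), 1.96)
  expect_equal(crosstab_pct(56, 6067), 0.92)
  expect_equal(crosstab_pct(529, 9779), 5.41)
  expect_equal(crosstab_pct(642, 9779), 6.57)
  expect_equal(crosstab_pct(0, 500), 0)

  sim <- shared_sim()
  map <- map_sites_to_promoters(sim$sites, sim$promoters, quiet = TRUE)
  pm <- promoter_methylation(sim$beta, map)
  dmp <- identify_dmps(pm, meth_samples(sim), genes = sim$genes)
  classes <- shared_classes()
  tab <- dmp_crosstab(dmp, classes)
  expect_equal(tab$hyper_pct, crosstab_pct(tab$hyper, tab$total))
  expect_equal(tab$hypo_pct, crosstab_pct(tab$hypo, tab$total))
  # class-cell totals sum to the per-biotype totals
  cells <- tab[tab$cls != "total", ]
  tot <- tab[tab$cls == "total", ]
  for (bt in tot$biotype) {
    expect_equal(sum(cells$total[cells$biotype == bt]),
                 tot$total[tot$biotype == bt])
  }
  # unknown gene -> error
  rogue <- dmp
  rogue$gene_id[1] <- "NOT_A_GENE"
  expect_error(dmp_crosstab(rogue, classes), "missing from the classes")
})
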