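test_that("correlation test matches the closed-form t conversion", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_test(x, 2 * x + 3)$r, 1)
  expect_equal(correlation_test(x, 2 * x + 3)$p, 0)
  expect_equal(correlation_test(x, -x)$r, -1)
  y <- c(1.1, 1.9, 3.2, 3.8)
  got <- correlation_test(x, y)
  r <- cor(x, y)
  expect_equal(got$r, r)
  expect_equal(got$p, 2 * pt(-abs(r) * sqrt((4 - 2) / (1 - r^2)), df = 2))
  # independent reference: cor.test
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  expect_true(is.na(correlation_test(x, rep(1, 4))$r))
  expect_error(correlation_test(1:2, 1:2), "at least 3")
})

# a star fixture: one lncRNA linearly driving five mRNAs, plus noise genes
star_fixture <- function() {
  set.seed(8)
  s <- paste0("s", 1:6)
  hub <- rnorm(6)
  mrna <- rbind(
    t(sapply(1:5, function(i) i * hub + i)),       # r = 1 with the hub
    matrix(rnorm(18), nrow = 3)                    # independent
  )
  rownames(mrna) <- c(paste0("M", 1:5), paste0("N", 1:3))
  lnc <- rbind(hub, matrix(rnorm(12), nrow = 2))
  rownames(lnc) <- c("HUB", "L1", "L2")
  list(
    mrna = tibble::as_tibble(`colnames<-`(mrna, s), rownames = "gene_id"),
    lnc = tibble::as_tibble(`colnames<-`(lnc, s), rownames = "gene_id"),
    cand = tibble::tibble(
      feature_id = c(rownames(mrna), rownames(lnc)),
      biotype = rep(c("mRNA", "lncRNA"), c(8, 3))
    )
  )
}

test_that("the network is bipartite with degrees matching an edge recount", {
  fx <- star_fixture()
  suppressMessages(net <- build_network(fx$mrna, fx$lnc, fx$cand))
  expect_equal(net$degrees$degree[net$degrees$node == "HUB"], 5)
  expect_equal(net$n_edges, 5)
  # bipartite: every edge joins a lncRNA candidate to an mRNA candidate
  expect_true(all(net$edges$lncrna_id %in% c("HUB", "L1", "L2")))
  expect_true(all(net$edges$mrna_id %in% paste0("M", 1:5)))
  # degree sum = 2 x edges; degrees equal a brute-force recount
  expect_equal(sum(net$degrees$degree), 2 * net$n_edges)
  recount <- table(c(net$edges$lncrna_id, net$edges$mrna_id))
  for (nd in names(recount)) {
    expect_equal(net$degrees$degree[net$degrees$node == nd],
                 unname(recount[[nd]]))
  }
})

test_that("edge thresholds are strict: r must exceed the cut", {
  fx <- star_fixture()
  m <- as.matrix(fx$mrna[-1]); rownames(m) <- fx$mrna$gene_id
  l <- as.matrix(fx$lnc[-1]); rownames(l) <- fx$lnc$gene_id
  r_exact <- cor(l["HUB", ], m["M1", ])  # 1 up to fp
  at_cut <- build_network(fx$mrna, fx$lnc,
                          tibble::tibble(feature_id = c("HUB", "M1"),
                                         biotype = c("lncRNA", "mRNA")),
                          r_cut = r_exact)
  expect_equal(at_cut$n_edges, 0)
  below_cut <- build_network(fx$mrna, fx$lnc,
                             tibble::tibble(feature_id = c("HUB", "M1"),
                                            biotype = c("lncRNA", "mRNA")),
                             r_cut = r_exact - 1e-9)
  expect_equal(below_cut$n_edges, 1)
  # negative perfect correlation is excluded under the signed reading
  neg <- fx
  neg$lnc[neg$lnc$gene_id == "HUB", -1] <- -neg$lnc[neg$lnc$gene_id == "HUB", -1]
  suppressMessages(net_neg <- build_network(neg$mrna, neg$lnc, fx$cand))
  expect_equal(net_neg$n_edges, 0)
  suppressMessages(net_abs <- build_network(neg$mrna, neg$lnc, fx$cand,
                                            absolute = TRUE))
  expect_equal(net_abs$n_edges, 5)
})

test_that("raising the correlation cut never adds edges", {
  sim <- shared_sim()
  cand <- tibble::tibble(
    feature_id = c(sim$expr_mrna$gene_id, sim$expr_lncrna$gene_id),
    biotype = rep(c("mRNA", "lncRNA"),
                  c(nrow(sim$expr_mrna), nrow(sim$expr_lncrna)))
  )
  cuts <- c(0.90, 0.95, 0.98, 0.999)
  nets <- lapply(cuts, function(rc)
    build_network(sim$expr_mrna, sim$expr_lncrna, cand, r_cut = rc))
  key <- function(n) paste(n$edges$lncrna_id, n$edges$mrna_id)
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(key(nets[[i + 1]]) %in% key(nets[[i]])))
  }
  # planted pairs survive the default threshold
  tr_key <- paste(sim$truth$planted_edges$lncrna_id,
                  sim$truth$planted_edges$mrna_id)
  expect_true(all(tr_key %in% key(nets[[3]])))
})

test_that("hubs are ranked by degree with ties broken by id", {
  deg <- tibble::tibble(node = c("a", "b", "c"), type = "mRNA",
                        degree = c(3L, 1L, 3L))
  net <- structure(list(edges = tibble::tibble(), degrees = deg,
                        n_nodes = 3, n_edges = 0, r_cut = 0.98,
                        p_cut = 0.01, absolute = FALSE),
                   class = "coexpression_network")
  expect_equal(rank_hubs(net, 3)$node, c("a", "c", "b"))
  expect_equal(nrow(rank_hubs(net, 2)), 2)
  expect_error(rank_hubs(net, 0), "positive")
  # empty candidate set -> empty network, empty hub list
  fx <- star_fixture()
  empty <- build_network(fx$mrna, fx$lnc,
                         tibble::tibble(feature_id = character()))
  expect_equal(empty$n_edges, 0)
  expect_equal(nrow(rank_hubs(empty, 5)), 0)
})

test_that("SIF export writes one interaction line per edge", {
  fx <- star_fixture()
  suppressMessages(net <- build_network(fx$mrna, fx$lnc, fx$cand))
  f <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, f)
  lines <- readLines(f)
  expect_length(lines, net$n_edges)
  expect_true(all(grepl("^\\S+\tcoexp\t\\S+$", lines)))
})
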