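test_that("quantile normalization matches the sort-average brute force", {
  toy <- tibble::tibble(id = paste0("g", 1:4),
                        s1 = c(1, 3, 5, 7), s2 = c(2, 4, 6, 8))
  qn <- quantile_normalize(toy)
  expect_equal(qn$s1, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(qn$s2, c(1.5, 3.5, 5.5, 7.5))
  # random matrix, incl. within-column ties
  set.seed(42)
  m <- matrix(round(rnorm(60, 8, 2), 1), nrow = 12,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  tb <- tibble::as_tibble(m, rownames = "id")
  got <- as.matrix(quantile_normalize(tb)[-1])
  expect_equal(got, unname(oracle_quantile_normalize(m)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("quantile normalization is idempotent and equalises column sums", {
  set.seed(7)
  tb <- tibble::as_tibble(matrix(rexp(80, 0.2), nrow = 16,
                                 dimnames = list(paste0("g", 1:16),
                                                 paste0("s", 1:5))),
                          rownames = "id")
  q1 <- quantile_normalize(tb)
  q2 <- quantile_normalize(q1)
  expect_equal(q1, q2, tolerance = 1e-12)
  sums <- colSums(as.matrix(q1[-1]))
  expect_lt(diff(range(sums)), 1e-9 * mean(sums))
  # already-identical columns and single columns are fixed points
  same <- tibble::tibble(id = paste0("g", 1:3), a = c(1, 5, 9), b = c(1, 5, 9))
  expect_equal(quantile_normalize(same), same)
  one <- tibble::tibble(id = paste0("g", 1:3), a = c(2, 4, 8))
  expect_equal(quantile_normalize(one), one)
  # upper-quartile scaling equalises the 75th percentiles
  uq <- quantile_normalize(tb, method = "upper_quartile")
  q3 <- apply(as.matrix(uq[-1]), 2, quantile, probs = 0.75)
  expect_lt(diff(range(q3)), 1e-9)
})

test_that("differential expression matches a per-feature t.test oracle", {
  set.seed(13)
  n_feat <- 40
  m <- matrix(rnorm(n_feat * 6, 8, 0.5), nrow = n_feat,
              dimnames = list(paste0("g", 1:n_feat),
                              c(paste0("c", 1:3), paste0("u", 1:3))))
  m[1:5, 4:6] <- m[1:5, 4:6] + 2   # planted up
  tb <- tibble::as_tibble(m, rownames = "feature_id")
  de <- differential_expression(tb, toy_samples(3, 3))
  for (g in c("g1", "g3", "g20", "g40")) {
    tt <- t.test(m[g, 4:6], m[g, 1:3], var.equal = TRUE)
    row <- de[de$feature_id == g, ]
    expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
    expect_equal(row$log2fc, mean(m[g, 4:6]) - mean(m[g, 1:3]))
  }
  expect_equal(de$fdr, p.adjust(de$p, "BH"), tolerance = 1e-12)
  expect_true(all(de$fdr >= 0 & de$fdr <= 1))
  # fdr is non-decreasing in p-rank after step-up enforcement
  expect_true(all(diff(de$fdr[order(de$p)]) >= -1e-15))
})

test_that("planted strong effects are called with the right direction", {
  set.seed(99)
  m <- matrix(rnorm(30 * 6, 8, 0.1), nrow = 30,
              dimnames = list(paste0("g", 1:30),
                              c(paste0("c", 1:3), paste0("u", 1:3))))
  m[1, 4:6] <- m[1, 4:6] + 2
  de <- differential_expression(tibble::as_tibble(m, rownames = "feature_id"),
                                toy_samples(3, 3))
  expect_true(de[de$feature_id == "g1", ]$is_de)
  expect_equal(de[de$feature_id == "g1", ]$direction, "up")
  expect_equal(de$feature_id[1], "g1")  # sorted by fdr
})

test_that("the DE call is strict at both thresholds", {
  # feature with log2fc exactly 1 and tiny p: |log2fc| > 1 fails
  vals <- list(
    exact1 = c(5, 5.1, 4.9, 6, 6.1, 5.9),
    null = c(8, 8, 8, 8, 8, 8)
  )
  tb <- toy_expr(vals, c(paste0("c", 1:3), paste0("u", 1:3)))
  de <- differential_expression(tb, toy_samples(3, 3))
  ex <- de[de$feature_id == "exact1", ]
  expect_equal(ex$log2fc, 1)
  expect_lt(ex$fdr, 0.05)
  expect_false(ex$is_de)
  # zero variance in both groups with equal means -> p = 1
  nul <- de[de$feature_id == "null", ]
  expect_equal(nul$log2fc, 0)
  expect_equal(nul$p, 1)
  expect_false(nul$is_de)
  expect_equal(nul$direction, "none")
})

test_that("group sizes below 2 are rejected", {
  tb <- toy_expr(list(g1 = c(1, 2, 3)), c("c1", "u1", "u2"))
  s <- tibble::tibble(sample_id = c("c1", "u1", "u2"),
                      group = c("ctrl", "uc", "uc"))
  expect_error(differential_expression(tb, s), ">= 2 samples")
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  sim <- shared_sim()
  chk <- label_swap_check(quantile_normalize(sim$expr_mrna),
                          expr_samples(sim))
  expect_true(chk$ok)
  expect_lte(chk$max_abs_log2fc_sum, 1e-12)
  expect_lte(chk$max_abs_p_diff, 1e-12)
})
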