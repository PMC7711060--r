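# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# A moderate cohort reused by several test files (built lazily, cached).
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_cohort(
      sim_config(n_genes_mrna = 60, n_genes_lncrna = 40,
                 n_planted_up_hypo = 2, n_planted_down_hyper = 1,
                 seed = 101)
    )
  }
  .fixture_env$sim
}

shared_classes <- function() {
  if (is.null(.fixture_env$classes)) {
    .fixture_env$classes <- classify_promoters(shared_sim()$promoters)
  }
  .fixture_env$classes
}

meth_samples <- function(sim) sim$samples[sim$samples$assay == "meth", ]
expr_samples <- function(sim) sim$samples[sim$samples$assay == "expr", ]

# Random DNA of given GC content.
random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Two-group expression toy: one feature per row of `means_ctrl`/`means_case`.
toy_expr <- function(values, sample_ids) {
  m <- do.call(rbind, values)
  tibble::tibble(feature_id = names(values)) |>
    dplyr::bind_cols(tibble::as_tibble(matrix(m, nrow = length(values),
                                              dimnames = list(NULL, sample_ids))))
}

toy_samples <- function(n_ctrl, n_case) {
  tibble::tibble(
    sample_id = c(paste0("c", seq_len(n_ctrl)), paste0("u", seq_len(n_case))),
    group = c(rep("ctrl", n_ctrl), rep("uc", n_case))
  )
}
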