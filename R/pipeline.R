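#' Configuration for an end-to-end pipeline run
#'
#' Bundles the synthetic-cohort configuration with every stage parameter:
#' promoter scan window and class thresholds, differential expression cuts,
#' DMP tail fraction, network thresholds, and the number of hub predictors
#' fed to the diagnostic model.
#'
#' @param sim A [sim_config()] describing the cohort to simulate.
#' @param window,hcp_ratio,hcp_gc,lcp_ratio,step Promoter classification
#'   parameters (see [classify_promoter()]).
#' @param lfc_cut,fdr_cut Differential expression thresholds.
#' @param tail_fraction DMP tail fraction.
#' @param r_cut,p_cut Co-expression edge thresholds.
#' @param n_predictors Number of top hub mRNAs used as diagnostic
#'   predictors (default 3).
#' @param test_seed_offset Seed offset for the independent test cohort drawn
#'   with the same planted truth (default 104729).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), window = 500L,
                            hcp_ratio = 0.75, hcp_gc = 0.55,
                            lcp_ratio = 0.48, step = 1L,
                            lfc_cut = 1.0, fdr_cut = 0.05,
                            tail_fraction = 0.05,
                            r_cut = 0.98, p_cut = 0.01,
                            n_predictors = 3L,
                            test_seed_offset = 104729L) {
  structure(list(
    sim = sim, window = as.integer(window), hcp_ratio = hcp_ratio,
    hcp_gc = hcp_gc, lcp_ratio = lcp_ratio, step = as.integer(step),
    lfc_cut = lfc_cut, fdr_cut = fdr_cut, tail_fraction = tail_fraction,
    r_cut = r_cut, p_cut = p_cut, n_predictors = as.integer(n_predictors),
    test_seed_offset = as.integer(test_seed_offset)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every invariant and returns the violations instead of erroring,
#' so configurations can be linted before a run.
#'
#' @param config A [pipeline_config()].
#' @return A character vector of violation messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  sim_err <- tryCatch({
    validate_sim_config(config$sim)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(sim_err)) v <- c(v, sim_err)
  chk(config$window >= 100, "window: must be >= 100 bp")
  chk(config$step >= 1, "step: must be >= 1")
  chk(config$hcp_ratio > config$lcp_ratio,
      "hcp_ratio: must exceed lcp_ratio (classes must partition)")
  chk(config$hcp_gc > 0 && config$hcp_gc < 1, "hcp_gc: must lie in (0, 1)")
  chk(config$lcp_ratio > 0, "lcp_ratio: must be positive")
  chk(config$lfc_cut >= 0, "lfc_cut: must be non-negative")
  chk(config$fdr_cut >= 0 && config$fdr_cut <= 1,
      "fdr_cut: must lie in [0, 1]")
  chk(config$tail_fraction > 0 && config$tail_fraction < 0.5,
      "tail_fraction: must lie in (0, 0.5) for disjoint tails")
  chk(config$r_cut >= -1 && config$r_cut < 1, "r_cut: must lie in [-1, 1)")
  chk(config$p_cut > 0 && config$p_cut <= 1, "p_cut: must lie in (0, 1]")
  chk(config$n_predictors >= 1, "n_predictors: must be >= 1")
  v
}

run_stage <- function(name, report_env, n_records_fn, expr) {
  t0 <- Sys.time()
  result <- tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  entry <- list(
    stage = name,
    seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
    n_records = n_records_fn(result)
  )
  report_env$stages <- c(report_env$stages, list(entry))
  result
}

#' Run the whole pipeline on a synthetic cohort
#'
#' Executes, in order: simulate -> classify promoters -> differential
#' expression (mRNA and lncRNA separately, quantile normalized) ->
#' differential promoter methylation -> direction-concordant integration ->
#' lncRNA-mRNA co-expression network -> logistic diagnostic model (trained
#' on the simulated cohort, evaluated on an independent test cohort drawn
#' with the same planted truth). Any stage failure aborts with the stage
#' name; outputs produced so far are returned with the error via the
#' written files when `outdir` is set.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when set, every stage output is written
#'   (fixture files, `classes.tsv`, `de_mrna.tsv`, `de_lncrna.tsv`,
#'   `dmp.tsv`, `crosstab.tsv`, `candidates.tsv`, `edges.tsv`,
#'   `network.sif`, `degrees.tsv`, `model.json`, `run_report.json`).
#' @param quiet Suppress stage messages.
#' @return A list of class `methex_run`: `sim`, `classes`, `de_mrna`,
#'   `de_lncrna`, `dmp`, `crosstab`, `candidates`, `integration`,
#'   `network`, `hubs`, `model`, `roc_train`, `roc_test`, and `run_report`
#'   (stage ledger with parameters, input hashes, wall times and record
#'   counts).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = TRUE) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    rlang::abort(paste0("invalid pipeline config:\n  ",
                        paste(violations, collapse = "\n  ")))
  }
  env <- new.env()
  env$stages <- list()
  maybe_quiet <- if (quiet) suppressMessages else identity

  sim <- run_stage("simulate", env, function(x) nrow(x$genes),
                   simulate_cohort(config$sim))

  classes <- run_stage("classify_promoters", env, nrow, maybe_quiet(
    classify_promoters(sim$promoters, window = config$window,
                       hcp_ratio = config$hcp_ratio, hcp_gc = config$hcp_gc,
                       lcp_ratio = config$lcp_ratio, step = config$step)
  ))

  expr_samples <- sim$samples[sim$samples$assay == "expr", ]
  qn_mrna <- quantile_normalize(sim$expr_mrna)
  qn_lnc <- quantile_normalize(sim$expr_lncrna)
  de_mrna <- run_stage("de_mrna", env, function(x) sum(x$is_de),
    dplyr::mutate(differential_expression(qn_mrna, expr_samples,
                                          lfc_cut = config$lfc_cut,
                                          fdr_cut = config$fdr_cut),
                  biotype = "mRNA"))
  de_lnc <- run_stage("de_lncrna", env, function(x) sum(x$is_de),
    dplyr::mutate(differential_expression(qn_lnc, expr_samples,
                                          lfc_cut = config$lfc_cut,
                                          fdr_cut = config$fdr_cut),
                  biotype = "lncRNA"))

  meth_samples <- sim$samples[sim$samples$assay == "meth", ]
  dmp <- run_stage("dmp", env, function(x) sum(x$call != "none"), maybe_quiet({
    site_map <- map_sites_to_promoters(sim$sites, sim$promoters,
                                       quiet = quiet)
    pm <- promoter_methylation(sim$beta, site_map)
    identify_dmps(pm, meth_samples, genes = sim$genes,
                  tail_fraction = config$tail_fraction, site_map = site_map)
  }))
  crosstab <- dmp_crosstab(dmp, classes)

  de_all <- dplyr::bind_rows(de_mrna, de_lnc)
  candidates <- run_stage("integrate", env, nrow,
                          integrate_markers(de_all, dmp))
  integration <- integration_report(candidates, de_all)

  network <- run_stage("network", env, function(x) x$n_edges, maybe_quiet(
    build_network(qn_mrna, qn_lnc, candidates,
                  r_cut = config$r_cut, p_cut = config$p_cut)
  ))
  hubs <- if (network$n_nodes > 0) rank_hubs(network, top_k = 10L) else
    network$degrees

  diag_res <- run_stage("diagnose", env,
                        function(x) length(x$predictors), {
    hub_mrna <- hubs$node[hubs$type == "mRNA"]
    predictors <- utils::head(hub_mrna, config$n_predictors)
    if (length(predictors) == 0) {
      list(predictors = character(0), model = NULL,
           roc_train = NULL, roc_test = NULL, notes = "no candidate mRNA predictors; diagnostic stage skipped")
    } else {
      labels <- as.integer(expr_samples$group == "uc")
      train_x <- t(mat_from_tbl(qn_mrna)[predictors, , drop = FALSE])
      notes <- character(0)
      model <- withCallingHandlers(
        fit_logistic(as.data.frame(train_x), labels),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      test_cfg <- config$sim
      test_cfg$seed <- derive_seed(config$sim$seed, config$test_seed_offset)
      gt <- list(genes = sim$genes, truth = sim$truth)
      test_expr <- simulate_expression(gt$genes, gt$truth, test_cfg)
      test_x <- t(mat_from_tbl(quantile_normalize(test_expr$mrna))[predictors, , drop = FALSE])
      test_labels <- as.integer(test_expr$samples$group == "uc")
      list(
        predictors = predictors, model = model,
        roc_train = roc_auc(predict(model, as.data.frame(train_x), type = "link"),
                            labels),
        roc_test = roc_auc(predict(model, as.data.frame(test_x), type = "link"),
                           test_labels),
        notes = notes
      )
    }
  })

  run_report <- list(
    parameters = config[setdiff(names(config), "sim")],
    sim_config = unclass(config$sim),
    input_hashes = list(
      beta = rlang::hash(sim$beta), expr_mrna = rlang::hash(sim$expr_mrna),
      expr_lncrna = rlang::hash(sim$expr_lncrna),
      genes = rlang::hash(sim$genes)
    ),
    counts = list(
      n_genes = nrow(sim$genes),
      n_cpg_sites = nrow(sim$sites),
      n_de_mrna = sum(de_mrna$is_de),
      n_de_lncrna = sum(de_lnc$is_de),
      n_dmp = sum(dmp$call != "none"),
      n_candidates = nrow(candidates),
      n_edges = network$n_edges,
      auc_train = if (!is.null(diag_res$roc_train)) diag_res$roc_train$auc else NA,
      auc_test = if (!is.null(diag_res$roc_test)) diag_res$roc_test$auc else NA
    ),
    stages = env$stages
  )

  run <- structure(list(
    sim = sim, classes = classes, de_mrna = de_mrna, de_lncrna = de_lnc,
    dmp = dmp, crosstab = crosstab, candidates = candidates,
    integration = integration, network = network, hubs = hubs,
    model = diag_res$model, predictors = diag_res$predictors,
    roc_train = diag_res$roc_train, roc_test = diag_res$roc_test,
    run_report = run_report
  ), class = "methex_run")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fixture(sim, outdir)
    p <- function(f) file.path(outdir, f)
    readr::write_tsv(classes, p("classes.tsv"))
    readr::write_tsv(de_mrna, p("de_mrna.tsv"))
    readr::write_tsv(de_lnc, p("de_lncrna.tsv"))
    readr::write_tsv(dmp, p("dmp.tsv"))
    readr::write_tsv(crosstab, p("crosstab.tsv"))
    readr::write_tsv(candidates, p("candidates.tsv"))
    readr::write_tsv(network$edges, p("edges.tsv"))
    readr::write_tsv(network$degrees, p("degrees.tsv"))
    write_sif(network, p("network.sif"))
    if (!is.null(diag_res$model)) {
      jsonlite::write_json(list(
        predictors = diag_res$predictors,
        coefficients = as.list(diag_res$model$coefficients),
        converged = diag_res$model$converged,
        auc_train = diag_res$roc_train$auc,
        auc_test = diag_res$roc_test$auc
      ), p("model.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(run_report, p("run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.methex_run <- function(x, ...) {
  cnt <- x$run_report$counts
  cat("<methex_run> integrated methylation-expression pipeline\n")
  cat(sprintf("  genes: %d (%d CpG sites)\n", cnt$n_genes, cnt$n_cpg_sites))
  cat(sprintf("  DE: %d mRNA, %d lncRNA; DMP calls: %d\n",
              cnt$n_de_mrna, cnt$n_de_lncrna, cnt$n_dmp))
  cat(sprintf("  candidates: %d; network edges: %d\n",
              cnt$n_candidates, cnt$n_edges))
  if (!is.na(cnt$auc_train)) {
    cat(sprintf("  diagnostic AUC: %.3f train / %.3f test (%s)\n",
                cnt$auc_train, cnt$auc_test,
                paste(x$predictors, collapse = ", ")))
  }
  invisible(x)
}
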