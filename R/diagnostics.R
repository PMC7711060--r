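#' Fit a logistic diagnostic model by IRLS
#'
#' Maximum-likelihood logistic regression fit by iteratively reweighted
#' least squares, as used to combine candidate marker expression into a
#' disease-vs-control diagnostic score. Convergence is declared when the
#' largest coefficient change drops below `tol` (default 1e-8) within
#' `max_iter` iterations. Perfect separation (diverging coefficients /
#' fitted probabilities at 0 or 1) is detected and flagged with a warning:
#' `converged` is set to `FALSE` but predictions are still usable for
#' ranking. No regularization is applied.
#'
#' @param features A data frame or matrix of predictors, samples in rows
#'   (numeric columns only; a `sample_id` column is ignored). No missing
#'   values.
#' @param labels Binary response, one per sample: 0/1, logical, or a
#'   two-level factor (second level = case). Both classes must be present
#'   with at least 2 samples each.
#' @param tol,max_iter IRLS stopping rule.
#' @return An object of class `methex_logit`: `predictor_ids`,
#'   `coefficients` (named, intercept first), `intercept`, `converged`,
#'   `n_iter`, plus standard errors and fit statistics for [tidy()] and
#'   [glance()].
#' @seealso [predict.methex_logit()], [roc_auc()]
#' @export
fit_logistic <- function(features, labels, tol = 1e-8, max_iter = 100L) {
  if (is.data.frame(features)) {
    features <- features[setdiff(names(features), "sample_id")]
    features <- as.matrix(features)
  }
  if (!is.numeric(features)) rlang::abort("predictors must be numeric")
  if (anyNA(features)) rlang::abort("missing predictor values")
  y <- if (is.factor(labels)) {
    as.integer(labels) - 1L
  } else {
    as.integer(as.logical(labels) | labels == 1)
  }
  if (length(y) != nrow(features)) rlang::abort("labels/features length mismatch")
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    rlang::abort("need at least 2 samples in each class")
  }
  X <- cbind(rep(1, nrow(features)), features)
  pred_names <- colnames(features)
  if (is.null(pred_names)) {
    pred_names <- sprintf("x%d", seq_len(ncol(features)))
  }
  colnames(X) <- c("(Intercept)", pred_names)
  eps <- 1e-12
  dev_of <- function(mu) {
    -2 * sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  dev_old <- dev_of(rep(mean(y), length(y)))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(X * w)
    beta_new <- tryCatch(
      drop(solve(xtw %*% X, xtw %*% z)),
      error = function(e) rlang::abort("singular design in IRLS (collinear predictors?)")
    )
    if (any(!is.finite(beta_new))) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    mu_fit <- stats::plogis(drop(X %*% beta))
    dev_new <- dev_of(mu_fit)
    if (delta < tol) {
      converged <- TRUE
      break
    }
    # likelihood plateau while fitted probabilities saturate at 0/1 and the
    # sample is perfectly classified: coefficients are drifting outward
    if (abs(dev_new - dev_old) / (abs(dev_new) + 0.1) < tol &&
        all((mu_fit > 0.5) == (y == 1)) &&
        any(mu_fit < 1e-6 | mu_fit > 1 - 1e-6)) {
      separated <- TRUE
      break
    }
    dev_old <- dev_new
  }
  if (separated) {
    rlang::warn("perfect separation detected: coefficients diverge; predictions remain usable for ranking")
  } else if (!converged) {
    rlang::warn(sprintf("IRLS did not converge in %d iterations", max_iter))
  }
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  vcov <- tryCatch(solve(t(X * w) %*% X), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  eps <- 1e-12
  loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  p0 <- mean(y)
  loglik_null <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  structure(list(
    predictor_ids = colnames(X)[-1],
    coefficients = beta,
    intercept = unname(beta[1]),
    converged = converged,
    separated = separated,
    n_iter = iter,
    std_errors = sqrt(diag(vcov)),
    loglik = loglik,
    null_deviance = -2 * loglik_null,
    deviance = -2 * loglik,
    nobs = length(y)
  ), class = "methex_logit")
}

#' @export
print.methex_logit <- function(x, ...) {
  cat(sprintf("<methex_logit> %d predictor(s), %s in %d IRLS iteration(s)\n",
              length(x$predictor_ids),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict disease probabilities from a fitted logistic model
#'
#' @param object A `methex_logit`.
#' @param newdata Data frame or matrix holding the model's predictors (by
#'   name).
#' @param type `"response"` (probabilities, default) or `"link"` (log-odds).
#' @param ... Unused.
#' @return A numeric vector, one value per row of `newdata`.
#' @export
predict.methex_logit <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing_p <- setdiff(object$predictor_ids, names(newdata))
    if (length(missing_p) > 0) {
      rlang::abort(paste0("newdata lacks predictor(s): ",
                          paste(missing_p, collapse = ", ")))
    }
    newdata <- as.matrix(newdata[object$predictor_ids])
  }
  eta <- drop(cbind(1, newdata) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @rdname fit_logistic
#' @param x A `methex_logit`.
#' @param ... Unused.
#' @export
tidy.methex_logit <- function(x, ...) {
  est <- x$coefficients
  se <- x$std_errors
  stat <- est / se
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pnorm(-abs(stat)))
  )
}

#' @rdname fit_logistic
#' @export
glance.methex_logit <- function(x, ...) {
  tibble::tibble(
    null.deviance = x$null_deviance, deviance = x$deviance,
    logLik = x$loglik, AIC = x$deviance + 2 * length(x$coefficients),
    nobs = x$nobs, converged = x$converged, n.iter = x$n_iter
  )
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique score values plus infinite endpoints
#' (a sample is called positive when its score is at or above the
#' threshold) and computes the AUC as the normalized Mann-Whitney statistic
#' with ties counted 0.5 - which equals the trapezoidal area under the step
#' curve, and the probability that a random case scores above a random
#' control.
#'
#' @param scores Numeric diagnostic scores, higher = more case-like.
#' @param labels Binary labels as in [fit_logistic()]; both classes
#'   required.
#' @return An object of class `methex_roc`: `thresholds`, `tpr`, `fpr`
#'   (parallel, curve from (0,0) to (1,1)), `auc`, `n_case`, `n_ctrl`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc # 1
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) rlang::abort("both classes must be present")
  if (anyNA(scores)) rlang::abort("missing scores")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 n_case = n1, n_ctrl = n0), class = "methex_roc")
}

#' @export
print.methex_roc <- function(x, ...) {
  cat(sprintf("<methex_roc> AUC = %.4f (%d case vs %d control)\n",
              x$auc, x$n_case, x$n_ctrl))
  invisible(x)
}

#' @rdname roc_auc
#' @param object A `methex_roc`.
#' @param ... Unused.
#' @export
autoplot.methex_roc <- function(object, ...) {
  df <- tibble::tibble(fpr = object$fpr, tpr = object$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Relative expression by the 2^-ddCt method
#'
#' Given mean cycle thresholds of a target and a reference gene in case and
#' control conditions, computes `dCt = Ct_target - Ct_reference` per
#' condition, `ddCt = dCt_case - dCt_ctrl`, and returns the fold change
#' `2^-ddCt` of the target in cases relative to controls.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Finite Ct
#'   values (vectorised).
#' @return Positive fold change(s).
#' @examples
#' ddct(20, 18, 24, 18) # 16
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) rlang::abort("all Ct values must be finite")
  ddct_val <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct_val)
}

#' 2^-ddCt fold changes from a long Ct table
#'
#' @param ct_table Data frame with columns `sample`, `group`, `gene`, `ct`
#'   (triplicate wells may appear as repeated rows; Ct values are averaged
#'   per gene x group).
#' @param reference Reference (housekeeping) gene name, e.g. `"GAPDH"`.
#' @param ref_group,case_group Group labels (defaults `"ctrl"`, `"uc"`).
#' @return A tibble with one row per target gene: `gene`, `dct_ctrl`,
#'   `dct_case`, `ddct`, `fold_change`.
#' @export
ddct_table <- function(ct_table, reference = "GAPDH",
                       ref_group = "ctrl", case_group = "uc") {
  stopifnot(all(c("group", "gene", "ct") %in% names(ct_table)))
  if (!reference %in% ct_table$gene) {
    rlang::abort(sprintf("reference gene '%s' not in the Ct table", reference))
  }
  means <- ct_table |>
    dplyr::filter(.data$group %in% c(ref_group, case_group)) |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "ct")
  ref_ct <- means[means$gene == reference, ]
  means |>
    dplyr::filter(.data$gene != reference) |>
    dplyr::mutate(
      dct_ctrl = .data[[ref_group]] - ref_ct[[ref_group]],
      dct_case = .data[[case_group]] - ref_ct[[case_group]],
      ddct = .data$dct_case - .data$dct_ctrl,
      fold_change = 2^(-.data$ddct)
    ) |>
    dplyr::select("gene", "dct_ctrl", "dct_case", "ddct", "fold_change")
}
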