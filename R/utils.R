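# Internal helpers shared across modules.

# Convert a "matrix tibble" (id column + one numeric column per sample) to a
# base matrix with rownames. `id_col` defaults to the first column.
mat_from_tbl <- function(x, id_col = NULL) {
  stopifnot(is.data.frame(x))
  id_col <- id_col %||% names(x)[1]
  ids <- as.character(x[[id_col]])
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate ids in column '%s'", id_col))
  }
  m <- as.matrix(x[setdiff(names(x), id_col)])
  if (!is.numeric(m)) rlang::abort("matrix tibble values must be numeric")
  rownames(m) <- ids
  m
}

tbl_from_mat <- function(m, id_col) {
  tibble::as_tibble(m, rownames = id_col)
}

# Sample ids of a group, in matrix column order.
group_samples <- function(samples, group, sample_ids,
                          sample_col = "sample_id", group_col = "group") {
  wanted <- samples[[sample_col]][samples[[group_col]] == group]
  intersect(sample_ids, wanted)
}

check_groups <- function(samples, sample_ids, ref, case,
                         min_n = 2L, sample_col = "sample_id",
                         group_col = "group") {
  ref_ids <- group_samples(samples, ref, sample_ids, sample_col, group_col)
  case_ids <- group_samples(samples, case, sample_ids, sample_col, group_col)
  if (length(ref_ids) < min_n || length(case_ids) < min_n) {
    rlang::abort(sprintf(
      "both groups need >= %d samples present in the matrix (found %d '%s', %d '%s')",
      min_n, length(ref_ids), ref, length(case_ids), case
    ))
  }
  list(ref = ref_ids, case = case_ids)
}

# Row-wise equal-variance two-sample t-test (case - ref), vectorised.
# Returns a tibble with mean_ref, mean_case, diff, t_stat, p.
# Zero pooled variance: diff == 0 -> t = 0, p = 1 (documented convention);
# diff != 0 -> t = +/-Inf, p = 0.
row_t_test <- function(m_ref, m_case, var_equal = TRUE) {
  n1 <- ncol(m_ref)
  n2 <- ncol(m_case)
  mean1 <- rowMeans(m_ref)
  mean2 <- rowMeans(m_case)
  v1 <- apply(m_ref, 1, var)
  v2 <- apply(m_case, 1, var)
  d <- mean2 - mean1
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- d / se
  zero_se <- !is.finite(t_stat)
  t_stat[zero_se & d == 0] <- 0
  t_stat[zero_se & d > 0] <- Inf
  t_stat[zero_se & d < 0] <- -Inf
  p <- 2 * pt(-abs(t_stat), df = df)
  p[zero_se & d == 0] <- 1
  p[zero_se & d != 0] <- 0
  tibble::tibble(
    mean_ref = unname(mean1), mean_case = unname(mean2),
    diff = unname(d), t_stat = unname(t_stat), p = unname(p)
  )
}

# Round half away from zero (k = round_half_up(0.05 * n) tail sizes).
round_half_up <- function(x) floor(x + 0.5)

# Derive a stage RNG seed from a root seed by a fixed offset, kept in
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}

`%||%` <- rlang::`%||%`
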