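# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops and substring arithmetic only.

# Exhaustive window scan using the scalar cpg_ratio/gc definitions on
# substrings, returning the class and every window's stats.
oracle_classify <- function(sequence, window = 500, hcp_ratio = 0.75,
                            hcp_gc = 0.55, lcp_ratio = 0.48) {
  L <- nchar(sequence)
  starts <- seq_len(L - window + 1)
  ratio <- numeric(length(starts))
  gc <- numeric(length(starts))
  for (i in seq_along(starts)) {
    w <- substr(sequence, starts[i], starts[i] + window - 1)
    chars <- strsplit(toupper(w), "")[[1]]
    n_c <- sum(chars == "C")
    n_g <- sum(chars == "G")
    n_cg <- sum(chars[-window] == "C" & chars[-1] == "G")
    ratio[i] <- if (n_c == 0 || n_g == 0) 0 else n_cg * window / (n_c * n_g)
    gc[i] <- (n_c + n_g) / window
  }
  cls <- if (any(ratio > hcp_ratio & gc > hcp_gc)) {
    "HCP"
  } else if (!any(ratio > lcp_ratio)) {
    "LCP"
  } else {
    "ICP"
  }
  list(cls = cls, ratio = ratio, gc = gc)
}

# Sort-average quantile normalization (ties get the mean reference value of
# their tied ranks).
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    # interpolate the reference at (possibly fractional) average ranks
    out[, j] <- stats::approx(seq_along(ref), ref, xout = r)$y
  }
  out
}

# O(n^2) pairwise AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# Double-loop site-to-promoter assignment.
oracle_site_map <- function(sites, promoters) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(promoters))) {
      if (sites$chrom[i] == promoters$chrom[j] &&
          sites$pos[i] >= promoters$start[j] &&
          sites$pos[i] < promoters$end[j]) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = promoters$gene_id[j], site_id = sites$site_id[i])
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$site_id), ]
}
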