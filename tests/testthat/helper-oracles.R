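# Independent reference implementations used as oracles. Each is written
# naively, straight from the defining formula, and stays independent of the
# package code paths it checks.

# position-by-position recount of the cohort sparseness score
ccs_brute <- function(mat, threshold = 10) {
  fracs <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    n_def <- 0L
    for (i in seq_len(nrow(mat))) {
      if (mat[i, s] < threshold) n_def <- n_def + 1L
    }
    fracs[s] <- n_def / nrow(mat)
  }
  median(fracs)
}

# literal neighbor scan for extrema: walk plateau runs, classify each run by
# the nearest differing values on either side; endpoints trough-only
extrema_brute <- function(v) {
  L <- length(v)
  peaks <- integer()
  troughs <- integer()
  if (L < 3L) return(list(peaks = peaks, troughs = troughs))
  i <- 1L
  while (i <= L) {
    j <- i
    while (j < L && v[j + 1L] == v[i]) j <- j + 1L
    left <- if (i > 1L) v[i - 1L] else NA_real_
    right <- if (j < L) v[j + 1L] else NA_real_
    center <- as.integer(floor((i + j) / 2))
    left_higher <- is.na(left) || left > v[i]
    right_higher <- is.na(right) || right > v[i]
    left_lower <- is.na(left) || left < v[i]
    right_lower <- is.na(right) || right < v[i]
    whole <- is.na(left) && is.na(right)
    if (!whole && left_higher && right_higher) {
      troughs <- c(troughs, center)
    } else if (!whole && left_lower && right_lower &&
                 center > 1L && center < L) {
      peaks <- c(peaks, center)
    }
    i <- j + 1L
  }
  list(peaks = peaks, troughs = troughs)
}

# naive locally weighted degree-1 fit via lm.wfit, same window/weight
# definitions: k = max(ceil(span*L), 4) nearest points, tricube weights,
# distance ties toward the lower index
lowess_reference <- function(y, span) {
  L <- length(y)
  k <- min(max(ceiling(span * L), 4L), L)
  out <- numeric(L)
  for (i in seq_len(L)) {
    d <- abs(seq_len(L) - i)
    ord <- order(d, seq_len(L))
    idx <- sort(ord[seq_len(k)])
    dd <- abs(idx - i)
    dmax <- max(dd)
    w <- if (dmax == 0) rep(1, k) else (1 - (dd / dmax)^3)^3
    X <- cbind(1, idx - i)
    fit <- stats::lm.wfit(X, y[idx], w)
    out[i] <- fit$coefficients[1L]
  }
  out
}

# textbook Pearson correlation
pearson_textbook <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# textbook Friedman statistic: 12/(n k (k+1)) * sum R_j^2 - 3 n (k+1),
# average ranks within rows
friedman_textbook <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  R <- colSums(t(apply(m, 1L, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# textbook Pearson chi-square for a contingency table
chisq_textbook <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# small cohort builder: one region of length L with given per-sample columns
toy_matrix <- function(...) {
  cols <- list(...)
  do.call(cbind, lapply(cols, as.integer))
}

# a single-region catalog + depth_matrix from an L x n integer matrix
toy_depth_matrix <- function(mat, gene = "G", chrom = "chr1", start = 0L) {
  cat <- region_catalog(gene, chrom, start, start + nrow(mat))
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  structure(list(catalog = cat, samples = colnames(mat),
                 depths = stats::setNames(list(mat), cat$region_id)),
            class = "depth_matrix")
}
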