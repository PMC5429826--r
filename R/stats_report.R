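#' Cohort summary of low-coverage genes
#'
#' Counts genes above the two CCS cuts (strict inequalities; the severe
#' column is nested inside the low column, so every gene above the upper cut
#' is also counted above the lower one).
#'
#' @param gene_results output of \code{\link{gene_ccs}}.
#' @param cuts the two CCS cuts (default \code{c(0.2, 0.5)}).
#' @return One-row \code{data.frame}: n_genes, n_ccs_gt_0.2, pct_ccs_gt_0.2,
#'   n_ccs_gt_0.5, pct_ccs_gt_0.5 (percentages to one decimal).
#' @export
summary_table <- function(gene_results, cuts = c(0.2, 0.5)) {
  stopifnot(nrow(gene_results) >= 1L)
  n <- nrow(gene_results)
  n1 <- sum(gene_results$ccs > cuts[1L])
  n2 <- sum(gene_results$ccs > cuts[2L])
  out <- data.frame(n_genes = n, n1 = n1, p1 = round(100 * n1 / n, 1L),
                    n2 = n2, p2 = round(100 * n2 / n, 1L))
  names(out) <- c("n_genes", sprintf("n_ccs_gt_%g", cuts[1L]),
                  sprintf("pct_ccs_gt_%g", cuts[1L]),
                  sprintf("n_ccs_gt_%g", cuts[2L]),
                  sprintf("pct_ccs_gt_%g", cuts[2L]))
  out
}

#' Pearson correlation between region length and unevenness
#'
#' @param ue_results output of \code{\link{ue_for_matrix}}.
#' @return List: \code{r} (sample Pearson correlation, \code{NA} when either
#'   variable has zero variance), \code{n}.
#' @export
pearson_length_ue <- function(ue_results) {
  ok <- is.finite(ue_results$ue)
  L <- ue_results$length[ok]
  u <- ue_results$ue[ok]
  if (length(u) < 3L) stop("need at least 3 regions with finite U_E")
  if (stats::sd(L) == 0 || stats::sd(u) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, n = length(u)))
  }
  list(r = stats::cor(L, u), n = length(u))
}

#' Friedman test across matched regions
#'
#' Rank-based test for differences between K platforms measured on the same R
#' regions (a matched complete design). Uses the plain Friedman statistic with
#' average ranks for ties and no tie correction, so a fully tied matrix scores
#' exactly 0; the p-value comes from the chi-square approximation with
#' df = K - 1.
#'
#' @param scores numeric matrix, regions in rows, platforms in columns; no
#'   missing cells.
#' @param min_length optional vector of region lengths paired with rows;
#'   rows with length <= \code{length_cut} are dropped before testing.
#' @param length_cut minimum region length in bp applied when
#'   \code{min_length} is given (default 400, strict >).
#' @return List: \code{statistic}, \code{df}, \code{p_value},
#'   \code{p_display} (floored at the 2.2e-16 machine-precision convention),
#'   \code{n_regions}.
#' @export
friedman_test <- function(scores, min_length = NULL, length_cut = 400) {
  scores <- as.matrix(scores)
  if (any(is.na(scores))) stop("matched design requires complete scores")
  if (!is.null(min_length)) {
    stopifnot(length(min_length) == nrow(scores))
    scores <- scores[min_length > length_cut, , drop = FALSE]
  }
  n <- nrow(scores)
  k <- ncol(scores)
  if (n < 2L || k < 2L) stop("need >= 2 regions and >= 2 platforms")
  ranks <- t(apply(scores, 1L, rank))
  Rj <- colSums(ranks)
  statistic <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  df <- k - 1L
  p <- stats::pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p_value = p,
       p_display = format_pvalue(p), n_regions = n)
}

format_pvalue <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3, scientific = TRUE)
}

#' Manhattan-style per-gene CCS table
#'
#' One row per gene ordered along the genome, with a cumulative x coordinate
#' for genome-wide plotting: each chromosome's genes are offset by the prefix
#' sum of the extents (maximum region end) of the preceding chromosomes.
#'
#' @param gene_results output of \code{\link{gene_ccs}}.
#' @return \code{data.frame}: gene, chrom, start, ccs, class, x (cumulative
#'   coordinate), ordered by (chrom, start).
#' @export
manhattan_table <- function(gene_results) {
  g <- gene_results[order(chrom_rank(gene_results$chrom),
                          gene_results$start), , drop = FALSE]
  chroms <- unique(g$chrom)
  extent <- vapply(chroms, function(ch) max(g$end[g$chrom == ch]),
                   numeric(1))
  offset <- c(0, cumsum(as.numeric(extent)))[seq_along(chroms)]
  names(offset) <- chroms
  out <- data.frame(gene = g$gene, chrom = g$chrom, start = g$start,
                    ccs = g$ccs, class = g$class,
                    x = unname(offset[g$chrom]) + g$start,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a data frame as a versioned TSV
#'
#' Output files carry a comment-prefixed header line with the package version
#' so every table records the code that produced it.
#'
#' @param df data frame to write.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# exomecov ",
                    as.character(utils::packageVersion("exomecov"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
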