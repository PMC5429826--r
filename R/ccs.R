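#' Fraction of deficient bases in one depth profile
#'
#' A base is deficient when its read depth is strictly below the cutoff
#' (default 10 reads); a base at exactly the cutoff is adequately covered.
#'
#' @param depths integer vector of per-base depths for one region in one
#'   sample.
#' @param threshold deficiency cutoff in reads (default 10).
#' @return Fraction in [0, 1] with denominator L_R.
#' @export
deficient_fraction <- function(depths, threshold = 10) {
  if (length(depths) == 0L) stop("empty depth profile")
  mean(depths < threshold)
}

#' Cohort Coverage Sparseness score for one region
#'
#' The CCS score of a region is the cohort median, across samples, of the
#' per-sample fraction of region bases covered by fewer than \code{threshold}
#' reads. It runs from 0 (every base adequately covered in at least half the
#' cohort) to 1 (every base deficient in at least half the cohort). For an
#' even number of samples the median is the midpoint of the two central
#' order statistics.
#'
#' @param region_mat integer matrix of depths, L_R rows by n_samples columns.
#' @param threshold deficiency cutoff in reads (default 10).
#' @return List with \code{ccs}, \code{per_sample_deficient_fraction} (named
#'   by sample) and \code{n_samples}.
#' @export
ccs_score <- function(region_mat, threshold = 10) {
  if (is.null(dim(region_mat)) || ncol(region_mat) == 0L) {
    stop("ccs_score requires at least one sample")
  }
  if (nrow(region_mat) == 0L) stop("empty region")
  frac <- colMeans(region_mat < threshold)
  list(ccs = stats::median(frac), per_sample_deficient_fraction = frac,
       n_samples = ncol(region_mat))
}

#' Per-exon CCS scores for a cohort
#'
#' @param matrix a \code{depth_matrix} (normally after \code{\link{qc_filter}}).
#' @param threshold deficiency cutoff in reads (default 10).
#' @return \code{data.frame}: region_id, gene, chrom, start, end, length, ccs,
#'   class, n_samples — one row per catalog region, in catalog order.
#' @export
exon_ccs <- function(matrix, threshold = 10) {
  stopifnot(inherits(matrix, "depth_matrix"))
  cat <- matrix$catalog
  ccs <- vapply(matrix$depths, function(m) ccs_score(m, threshold)$ccs,
                numeric(1))
  data.frame(region_id = cat$region_id, gene = cat$gene, chrom = cat$chrom,
             start = cat$start, end = cat$end, length = cat$length,
             ccs = unname(ccs), class = classify_ccs(unname(ccs)),
             n_samples = length(matrix$samples), stringsAsFactors = FALSE)
}

#' Per-gene CCS scores for a cohort
#'
#' A gene's region of interest is the union of its exonic bases: per sample,
#' deficient bases are counted over all the gene's regions and divided by the
#' gene's total exonic length, and the cohort median of those pooled fractions
#' is the gene CCS. \code{method = "exon_median"} instead aggregates the
#' per-exon CCS scores by their median (alternative aggregation, off by
#' default).
#'
#' @param matrix a \code{depth_matrix}.
#' @param threshold deficiency cutoff in reads (default 10).
#' @param method \code{"pooled"} (default) or \code{"exon_median"}.
#' @return \code{data.frame}: gene, chrom, start, end, length (total exonic
#'   bp), n_exons, ccs, class, n_samples — one row per gene, ordered by
#'   (chrom, start).
#' @export
gene_ccs <- function(matrix, threshold = 10,
                     method = c("pooled", "exon_median")) {
  stopifnot(inherits(matrix, "depth_matrix"))
  method <- match.arg(method)
  cat <- matrix$catalog
  genes <- unique(cat$gene)
  rows <- lapply(genes, function(g) {
    sel <- cat$gene == g
    rids <- cat$region_id[sel]
    L <- sum(cat$length[sel])
    if (method == "pooled") {
      counts <- Reduce(`+`, lapply(matrix$depths[rids],
                                   function(m) colSums(m < threshold)))
      ccs <- stats::median(counts / L)
    } else {
      ccs <- stats::median(vapply(matrix$depths[rids],
                                  function(m) ccs_score(m, threshold)$ccs,
                                  numeric(1)))
    }
    data.frame(gene = g, chrom = cat$chrom[sel][1L],
               start = min(cat$start[sel]), end = max(cat$end[sel]),
               length = L, n_exons = sum(sel), ccs = ccs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  out$class <- classify_ccs(out$ccs)
  out$n_samples <- length(matrix$samples)
  rownames(out) <- NULL
  out
}

#' Classify CCS scores into coverage classes
#'
#' Thresholds are strict: a gene is low-coverage only when CCS > 0.2 and
#' severe only when CCS > 0.5; the boundary values themselves are adequate
#' and low respectively.
#'
#' @param ccs numeric vector of CCS scores in [0, 1].
#' @param cuts the two class cut points (default \code{c(0.2, 0.5)}).
#' @return Character vector with levels adequate / low / severe.
#' @export
classify_ccs <- function(ccs, cuts = c(0.2, 0.5)) {
  if (any(is.na(ccs)) || any(ccs < 0) || any(ccs > 1)) {
    stop("CCS scores must lie in [0, 1]")
  }
  ifelse(ccs > cuts[2L], "severe", ifelse(ccs > cuts[1L], "low", "adequate"))
}

#' Chromosome-wise distribution of low-coverage genes
#'
#' Builds the 2 x K contingency table of low-coverage (CCS > cut) versus
#' adequate genes by chromosome and tests homogeneity with Pearson's
#' chi-square (no continuity correction, df = K - 1).
#'
#' @param gene_results output of \code{\link{gene_ccs}}.
#' @param cut low-coverage CCS cut (default 0.2, strict).
#' @return List: \code{table} (data.frame chrom, n_low, n_adequate),
#'   \code{statistic}, \code{df}, \code{p_value},
#'   \code{small_expected_counts} (TRUE when any expected cell < 1).
#' @export
chromosome_summary <- function(gene_results, cut = 0.2) {
  low <- gene_results$ccs > cut
  chroms <- unique(gene_results$chrom)
  if (length(chroms) < 2L) stop("need genes on at least 2 chromosomes")
  chroms <- chroms[order(chrom_rank(chroms))]
  tab <- t(vapply(chroms, function(ch) {
    sel <- gene_results$chrom == ch
    c(n_low = sum(low[sel]), n_adequate = sum(!low[sel]))
  }, c(n_low = 0, n_adequate = 0)))
  m <- as.matrix(tab)
  test <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(table = data.frame(chrom = chroms, n_low = m[, 1L],
                          n_adequate = m[, 2L], row.names = NULL,
                          stringsAsFactors = FALSE),
       statistic = unname(test$statistic), df = unname(test$parameter),
       p_value = unname(test$p.value),
       small_expected_counts = any(test$expected < 1))
}
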