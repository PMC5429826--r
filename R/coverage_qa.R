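#' Cohort coverage quality assessment
#'
#' The package's main entry point: runs sample QC, per-exon and per-gene CCS
#' scoring, per-region unevenness scoring, the Table-style cohort summary and
#' the chromosome-wise low-coverage distribution in one call, returning a
#' classed object with print/summary/plot methods.
#'
#' @param matrix a \code{depth_matrix} (see \code{\link{read_cohort}} or
#'   \code{\link{simulate_cohort}}).
#' @param deficiency_cutoff per-base deficiency cutoff in reads (default 10).
#' @param qc_min_depth sample QC threshold: minimum mean target depth
#'   (default 75; set to 0 to keep every sample).
#' @param ccs_cuts the two CCS class cuts (default \code{c(0.2, 0.5)}).
#' @param span LOWESS span for the unevenness score (default 0.03).
#' @param b_floor peak-base floor in reads (default 0.5).
#' @param platform optional platform label carried into the report.
#' @return An object of class \code{coverage_qa}: a list with \code{qc},
#'   \code{exon_ccs}, \code{gene_ccs}, \code{ue}, \code{summary},
#'   \code{chromosomes} (NULL with a single chromosome), \code{matrix}
#'   (the QC-filtered cohort) and the parameters used.
#' @export
coverage_qa <- function(matrix, deficiency_cutoff = 10, qc_min_depth = 75,
                        ccs_cuts = c(0.2, 0.5), span = 0.03, b_floor = 0.5,
                        platform = NA_character_) {
  stopifnot(inherits(matrix, "depth_matrix"))
  filt <- qc_filter(matrix, qc_min_depth)
  m <- filt$matrix
  ex <- exon_ccs(m, deficiency_cutoff)
  ge <- gene_ccs(m, deficiency_cutoff)
  ex$class <- classify_ccs(ex$ccs, ccs_cuts)
  ge$class <- classify_ccs(ge$ccs, ccs_cuts)
  ue <- ue_for_matrix(m, span = span, b_floor = b_floor)
  chrom <- if (length(unique(ge$chrom)) >= 2L) {
    chromosome_summary(ge, ccs_cuts[1L])
  }
  structure(list(qc = filt$qc, exon_ccs = ex, gene_ccs = ge, ue = ue,
                 summary = summary_table(ge, ccs_cuts),
                 chromosomes = chrom, matrix = m,
                 params = list(deficiency_cutoff = deficiency_cutoff,
                               qc_min_depth = qc_min_depth,
                               ccs_cuts = ccs_cuts, span = span,
                               b_floor = b_floor),
                 platform = platform),
            class = "coverage_qa")
}

#' @export
print.coverage_qa <- function(x, ...) {
  cat("Cohort coverage quality assessment",
      if (!is.na(x$platform)) paste0("(", x$platform, ")"), "\n")
  cat(sprintf("  samples: %d passing QC of %d (mean target depth >= %gX)\n",
              sum(x$qc$pass), nrow(x$qc), x$params$qc_min_depth))
  cat(sprintf("  regions: %d exons in %d genes\n", nrow(x$exon_ccs),
              nrow(x$gene_ccs)))
  s <- x$summary
  cat(sprintf("  genes with CCS > %g: %d (%.1f%%); CCS > %g: %d (%.1f%%)\n",
              x$params$ccs_cuts[1L], s[[2L]], s[[3L]],
              x$params$ccs_cuts[2L], s[[4L]], s[[5L]]))
  if (nrow(x$ue)) {
    cat(sprintf("  U_E: median %.2f, max %.2f over %d regions\n",
                stats::median(x$ue$ue), max(x$ue$ue), nrow(x$ue)))
  }
  invisible(x)
}

#' @export
summary.coverage_qa <- function(object, ...) {
  out <- list(summary = object$summary,
              class_counts = table(object$gene_ccs$class),
              qc = object$qc,
              chromosomes = object$chromosomes)
  class(out) <- "summary.coverage_qa"
  out
}

#' @export
print.summary.coverage_qa <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat("\nGene coverage classes:\n")
  print(x$class_counts)
  cat("\nSample QC:\n")
  print(x$qc, row.names = FALSE)
  if (!is.null(x$chromosomes)) {
    cat(sprintf("\nLow-coverage genes by chromosome: chi-square %.3f, df %d, p %s\n",
                x$chromosomes$statistic, x$chromosomes$df,
                format_pvalue(x$chromosomes$p_value)))
  }
  invisible(x)
}

#' Manhattan-style plot of per-gene CCS scores
#'
#' @param x a \code{coverage_qa} object.
#' @param ... passed to \code{plot}.
#' @export
plot.coverage_qa <- function(x, ...) {
  mt <- manhattan_table(x$gene_ccs)
  col <- c(adequate = "grey40", low = "steelblue", severe = "firebrick")
  graphics::plot(mt$x, mt$ccs, pch = 20, col = col[mt$class],
                 xlab = "cumulative genomic position (bp)",
                 ylab = "gene CCS", ylim = c(0, 1), ...)
  graphics::abline(h = x$params$ccs_cuts, lty = 2, col = "grey60")
  invisible(mt)
}
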