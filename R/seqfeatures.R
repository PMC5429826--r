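#' @importFrom Biostrings readDNAStringSet subseq letterFrequency
NULL

#' GC content of catalog regions
#'
#' GC fraction is (G+C)/(A+C+G+T) over the region's bases, case-insensitive;
#' ambiguous (non-ACGT) bases are excluded from the denominator and counted
#' separately. With \code{by = "gene"}, counts are pooled over a gene's
#' exonic bases before dividing.
#'
#' @param catalog a \code{\link{region_catalog}}.
#' @param fasta path to the reference FASTA (sequence names must include
#'   every catalog chromosome; descriptions after whitespace are ignored).
#' @param by \code{"region"} (default) or \code{"gene"}.
#' @return \code{data.frame}: region_id (or gene), gc_fraction, n_ambiguous.
#' @export
gc_content <- function(catalog, fasta, by = c("region", "gene")) {
  by <- match.arg(by)
  stopifnot(inherits(catalog, "region_catalog"))
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(catalog$chrom), names(seqs))
  if (length(missing)) {
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))
  }
  counts <- t(vapply(seq_len(nrow(catalog)), function(i) {
    s <- Biostrings::subseq(seqs[[catalog$chrom[i]]],
                            start = catalog$start[i] + 1L,
                            end = catalog$end[i])
    lf <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
    c(gc = unname(lf["C"] + lf["G"]), acgt = sum(lf),
      amb = length(s) - sum(lf))
  }, c(gc = 0, acgt = 0, amb = 0)))
  if (by == "region") {
    data.frame(region_id = catalog$region_id,
               gc_fraction = counts[, "gc"] / counts[, "acgt"],
               n_ambiguous = as.integer(counts[, "amb"]),
               stringsAsFactors = FALSE)
  } else {
    gc <- tapply(counts[, "gc"], catalog$gene, sum)
    acgt <- tapply(counts[, "acgt"], catalog$gene, sum)
    amb <- tapply(counts[, "amb"], catalog$gene, sum)
    genes <- unique(catalog$gene)
    data.frame(gene = genes, gc_fraction = unname(gc[genes] / acgt[genes]),
               n_ambiguous = as.integer(unname(amb[genes])),
               stringsAsFactors = FALSE)
  }
}

#' Group GC content by coverage class
#'
#' Splits region GC values into all / adequate (CCS <= cut) / low (CCS > cut)
#' groups and counts them in the three GC bands below 30%, 30-70% (inclusive)
#' and above 70%.
#'
#' @param gc output of \code{\link{gc_content}} (region level, with a key
#'   column matching \code{ccs}).
#' @param ccs a \code{data.frame} with the matching key column and a
#'   \code{ccs} column (\code{\link{exon_ccs}} or \code{\link{gene_ccs}}).
#' @param cut low-coverage CCS cut (default 0.2, strict).
#' @return List: \code{groups} (named list of GC vectors for all, adequate,
#'   low) and \code{bands} (\code{data.frame} of counts per group in the
#'   <30%, 30-70% and >70% GC bands).
#' @export
gc_class_densities <- function(gc, ccs, cut = 0.2) {
  key <- intersect(c("region_id", "gene"), intersect(names(gc), names(ccs)))
  if (length(key) == 0L) stop("no shared key column between gc and ccs")
  key <- key[1L]
  merged <- merge(gc, ccs[, c(key, "ccs")], by = key)
  if (nrow(merged) == 0L) stop("no overlapping ids between gc and ccs")
  groups <- list(all = merged$gc_fraction,
                 adequate = merged$gc_fraction[merged$ccs <= cut],
                 low = merged$gc_fraction[merged$ccs > cut])
  band <- function(x) {
    c(gc_below_30 = sum(x < 0.3), gc_30_to_70 = sum(x >= 0.3 & x <= 0.7),
      gc_above_70 = sum(x > 0.7))
  }
  bands <- as.data.frame(t(vapply(groups, band, c(0, 0, 0))))
  bands <- cbind(group = rownames(bands), bands, stringsAsFactors = FALSE)
  rownames(bands) <- NULL
  list(groups = groups, bands = bands)
}

# maximal run of values strictly below cut containing position p (1-based,
# half-open [first, last+1) in region coordinates)
trough_extent <- function(values, p, cut = 10) {
  if (values[p] >= cut) return(NULL)
  lo <- p
  while (lo > 1L && values[lo - 1L] < cut) lo <- lo - 1L
  hi <- p
  while (hi < length(values) && values[hi + 1L] < cut) hi <- hi + 1L
  c(lo, hi)
}

#' Concordance between extremely low coverage troughs and repeat elements
#'
#' A trough is extremely low when the smoothed cohort median drops below
#' \code{depth_cut} (default 10X); its extent is the maximal contiguous run of
#' smoothed median below the cut around the detected trough position. Region
#' endpoints below the cut count as troughs here, since a collapsed region
#' edge is a real coverage hole. A region with at least one such trough is
#' flagged when any repeat interval overlaps any of its trough extents by at
#' least 1 bp. The concordance fraction is reported over all flagged-eligible
#' regions and over those longer than 200 bp.
#'
#' @param matrix a \code{depth_matrix}.
#' @param repeats \code{data.frame} of repeat intervals (chrom, start, end;
#'   BED convention), e.g. from \code{\link{read_bed}}; \code{NULL} means no
#'   repeats, so nothing is flagged.
#' @param span LOWESS span (default 0.03).
#' @param depth_cut extremely-low cut in reads (default 10).
#' @return List: \code{per_region} (\code{data.frame}: region_id, length,
#'   n_low_troughs, min_trough_depth, repeat_overlap), \code{fraction}
#'   (flagged / regions with >= 1 low trough), \code{fraction_gt200} (same,
#'   regions > 200 bp only), \code{n_regions_with_troughs}.
#' @export
trough_repeat_concordance <- function(matrix, repeats, span = 0.03,
                                      depth_cut = 10) {
  stopifnot(inherits(matrix, "depth_matrix"))
  cat <- matrix$catalog
  sm <- smoothed_medians(matrix, span)
  rows <- lapply(names(sm), function(rid) {
    j <- match(rid, cat$region_id)
    v <- sm[[rid]]
    ex <- detect_extrema(v)
    cand <- sort(unique(c(ex$troughs,
                          if (v[1L] < depth_cut) 1L,
                          if (v[length(v)] < depth_cut) length(v))))
    extents <- unique(Filter(Negate(is.null),
                             lapply(cand, trough_extent, values = v,
                                    cut = depth_cut)))
    n_low <- length(extents)
    flag <- FALSE
    if (n_low > 0L && !is.null(repeats) && nrow(repeats) > 0L) {
      rep_ch <- repeats[repeats$chrom == cat$chrom[j], , drop = FALSE]
      for (e in extents) {
        # region-relative [lo, hi] -> genomic 0-based [start+lo-1, start+hi)
        gs <- cat$start[j] + e[1L] - 1L
        ge <- cat$start[j] + e[2L]
        if (any(rep_ch$start < ge & rep_ch$end > gs)) {
          flag <- TRUE
          break
        }
      }
    }
    data.frame(region_id = rid, length = cat$length[j], n_low_troughs = n_low,
               min_trough_depth = if (n_low) min(v) else NA_real_,
               repeat_overlap = flag, stringsAsFactors = FALSE)
  })
  per_region <- do.call(rbind, rows)
  with_troughs <- per_region[per_region$n_low_troughs > 0L, , drop = FALSE]
  frac <- if (nrow(with_troughs)) mean(with_troughs$repeat_overlap) else NA_real_
  long <- with_troughs[with_troughs$length > 200L, , drop = FALSE]
  frac200 <- if (nrow(long)) mean(long$repeat_overlap) else NA_real_
  list(per_region = per_region, fraction = frac, fraction_gt200 = frac200,
       n_regions_with_troughs = nrow(with_troughs))
}
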