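#' @importFrom IRanges IRanges reduce
#' @importFrom data.table fread
NULL

AUTOSOMES <- as.character(1:22)

norm_chrom <- function(chrom) sub("^chr", "", chrom)

is_autosome <- function(chrom) norm_chrom(chrom) %in% AUTOSOMES

#' Construct a region catalog
#'
#' A region catalog is the set of consensus exonic target regions over which
#' all coverage metrics are computed. Each region carries a unique identifier
#' (\code{gene|exon_index}), its gene symbol, its rank among the gene's
#' regions in ascending genomic order, and BED-convention coordinates
#' (0-based start, exclusive end).
#'
#' @param gene character vector of gene symbols (case-sensitive identity).
#' @param chrom chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions; must exceed \code{start}.
#' @param exon_index integer rank of the region within its gene, 0-based in
#'   ascending genomic order. Assigned automatically when \code{NULL}.
#' @param strand strand of the gene ("+", "-" or "*"); carried through but
#'   ignored by every metric, since depth is unstranded.
#' @return A \code{data.frame} of class \code{region_catalog} with columns
#'   \code{region_id}, \code{gene}, \code{exon_index}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{length}, sorted by
#'   (chrom, start).
#' @export
region_catalog <- function(gene, chrom, start, end, exon_index = NULL,
                           strand = "*") {
  n <- length(gene)
  if (n == 0L) {
    return(empty_catalog())
  }
  start <- as.integer(start)
  end <- as.integer(end)
  chrom <- rep_len(chrom, n)
  stopifnot(length(start) == n, length(end) == n)
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("invalid interval: start ", start[bad], " >= end ", end[bad],
         " (gene ", gene[bad], ")")
  }
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  strand <- rep_len(ifelse(strand %in% c("+", "-"), strand, "*"), n)
  ord <- order(chrom_rank(chrom), start, end)
  df <- data.frame(gene = gene[ord], chrom = chrom[ord], start = start[ord],
                   end = end[ord], strand = strand[ord],
                   stringsAsFactors = FALSE)
  if (is.null(exon_index)) {
    # rank within gene by genomic order (catalog already sorted)
    df$exon_index <- stats::ave(seq_len(n), df$gene,
                                FUN = function(i) seq_along(i) - 1L)
  } else {
    df$exon_index <- as.integer(exon_index)[ord]
  }
  df$region_id <- paste0(df$gene, "|", df$exon_index)
  if (anyDuplicated(df$region_id)) stop("duplicate region_id in catalog")
  ov <- overlapping_same_gene(df)
  if (ov) stop("overlapping regions of the same gene in catalog")
  df$length <- df$end - df$start
  df <- df[, c("region_id", "gene", "exon_index", "chrom", "start", "end",
               "strand", "length")]
  rownames(df) <- NULL
  class(df) <- c("region_catalog", "data.frame")
  df
}

empty_catalog <- function() {
  df <- data.frame(region_id = character(), gene = character(),
                   exon_index = integer(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   length = integer(), stringsAsFactors = FALSE)
  class(df) <- c("region_catalog", "data.frame")
  df
}

# order chromosomes numerically where possible, lexically otherwise
chrom_rank <- function(chrom) {
  x <- norm_chrom(chrom)
  num <- suppressWarnings(as.numeric(x))
  rank <- ifelse(is.na(num), 1e6 + as.integer(factor(x)), num)
  rank
}

overlapping_same_gene <- function(df) {
  any(vapply(split(df, df$gene), function(g) {
    g <- g[order(g$chrom, g$start), ]
    same <- g$chrom[-1L] == g$chrom[-nrow(g)]
    any(same & g$start[-1L] < g$end[-nrow(g)])
  }, logical(1)))
}

#' Merge transcript exons into a consensus per-gene region catalog
#'
#' Overlapping exons of the same gene, collected from different transcripts,
#' are merged into maximal disjoint intervals; the result is the consensus
#' exome annotation used by all downstream metrics. Genes whose transcripts
#' map to more than one chromosome are rejected with a diagnostic.
#'
#' @param exons a \code{data.frame} with columns \code{gene}, \code{chrom},
#'   \code{start} (0-based), \code{end} (exclusive) and optionally
#'   \code{strand} — one row per transcript exon, e.g. as returned by
#'   \code{\link{read_transcript_table}}.
#' @return A \code{\link{region_catalog}}.
#' @export
merge_transcript_exons <- function(exons) {
  if (nrow(exons) == 0L) return(empty_catalog())
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(exons)))
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  multi <- tapply(exons$chrom, exons$gene, function(x) length(unique(x)) > 1L)
  bad <- names(multi)[multi]
  if (length(bad)) {
    warning("rejecting gene(s) with exons on multiple chromosomes: ",
            paste(bad, collapse = ", "))
    exons <- exons[!exons$gene %in% bad, , drop = FALSE]
    if (nrow(exons) == 0L) return(empty_catalog())
  }
  parts <- lapply(split(exons, exons$gene), function(g) {
    r <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    strand <- if ("strand" %in% names(g)) g$strand[1L] else "*"
    data.frame(gene = g$gene[1L], chrom = g$chrom[1L],
               start = IRanges::start(r) - 1L, end = IRanges::end(r),
               strand = strand, stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, parts)
  region_catalog(merged$gene, merged$chrom, merged$start, merged$end,
                 strand = merged$strand)
}

#' Intersect a region catalog with capture-target intervals
#'
#' Restricts the catalog to bases present in both the catalog and the capture
#' targets; regions are split where targets fragment them and exon indices are
#' reassigned in ascending genomic order. Only autosomes (chromosomes 1-22,
#' with or without a "chr" prefix) are retained by default.
#'
#' @param catalog a \code{\link{region_catalog}}.
#' @param targets a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end} (BED convention), e.g. from \code{\link{read_bed}}.
#' @param autosomes_only drop non-autosomal regions (default \code{TRUE}).
#' @return A \code{\link{region_catalog}} restricted to the intersection; an
#'   empty catalog (with a warning) when nothing overlaps.
#' @export
intersect_targets <- function(catalog, targets, autosomes_only = TRUE) {
  stopifnot(inherits(catalog, "region_catalog"))
  if (autosomes_only) {
    catalog <- catalog[is_autosome(catalog$chrom), , drop = FALSE]
  }
  if (nrow(catalog) == 0L || nrow(targets) == 0L) {
    warning("no overlap between catalog and targets")
    return(empty_catalog())
  }
  if (any(targets$start >= targets$end)) stop("target with start >= end")
  pieces <- lapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    t <- targets[targets$chrom == row$chrom, , drop = FALSE]
    if (nrow(t) == 0L) return(NULL)
    tr <- IRanges::reduce(IRanges::IRanges(t$start + 1L, t$end))
    # clip each (merged) target to the region; targets are disjoint, so the
    # clipped pieces are the exact intersection
    s <- pmax(IRanges::start(tr), row$start + 1L)
    e <- pmin(IRanges::end(tr), row$end)
    keep <- s <= e
    if (!any(keep)) return(NULL)
    data.frame(gene = row$gene, chrom = row$chrom,
               start = s[keep] - 1L, end = e[keep],
               strand = row$strand, stringsAsFactors = FALSE)
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || nrow(pieces) == 0L) {
    warning("no overlap between catalog and targets")
    return(empty_catalog())
  }
  region_catalog(pieces$gene, pieces$chrom, pieces$start, pieces$end,
                 strand = pieces$strand)
}

#' Read a BED file of genomic intervals
#'
#' @param path a BED file with at least 3 tab-separated columns
#'   (chrom, start, end; 0-based half-open); columns 4-6 (name, score,
#'   strand) are kept when present.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end} and, if present, \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path,
         ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path, ": start >= end")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (all(nf >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write a region catalog as 6-column BED
#'
#' The name column is \code{gene|exon_index}; \code{\link{read_catalog}}
#' round-trips the file back into an identical catalog.
#'
#' @param catalog a \code{\link{region_catalog}}.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "region_catalog"))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", catalog$chrom, catalog$start,
                   catalog$end, catalog$region_id, catalog$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a region catalog written by \code{\link{write_catalog}}
#'
#' @param path a 6-column BED whose name column is \code{gene|exon_index}.
#' @return A \code{\link{region_catalog}}.
#' @export
read_catalog <- function(path) {
  bed <- read_bed(path)
  if (nrow(bed) == 0L) return(empty_catalog())
  if (is.null(bed$name)) stop("catalog BED requires a name column")
  gene <- sub("\\|[^|]*$", "", bed$name)
  idx <- as.integer(sub("^.*\\|", "", bed$name))
  strand <- if (is.null(bed$strand)) "*" else bed$strand
  region_catalog(gene, bed$chrom, bed$start, bed$end, exon_index = idx,
                 strand = strand)
}

#' Read a refFlat-style transcript table
#'
#' Expected tab-separated columns: gene symbol, transcript id, chromosome,
#' strand, comma-separated exon starts (0-based), comma-separated exon ends
#' (exclusive).
#'
#' @param path path to the table (no header).
#' @return \code{data.frame} with one row per exon: \code{gene},
#'   \code{transcript}, \code{chrom}, \code{strand}, \code{start}, \code{end}.
#' @export
read_transcript_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6L) stop("transcript table requires 6 columns")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    starts <- as.integer(strsplit(tab[i, 5L], ",")[[1L]])
    ends <- as.integer(strsplit(tab[i, 6L], ",")[[1L]])
    if (length(starts) != length(ends) || length(starts) == 0L) {
      stop("malformed exon lists on transcript table line ", i)
    }
    if (any(is.na(starts)) || any(is.na(ends)) || any(starts >= ends)) {
      stop("invalid exon coordinates on transcript table line ", i)
    }
    data.frame(gene = tab[i, 1L], transcript = tab[i, 2L],
               chrom = tab[i, 3L], strand = tab[i, 4L],
               start = starts, end = ends, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
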