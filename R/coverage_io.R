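#' Assemble a cohort depth matrix
#'
#' A depth matrix holds per-base integer read depths for every catalog region
#' and every sample. It is complete by construction: positions absent from a
#' sample's depth file are depth 0, never missing, because an uncaptured base
#' is a low-coverage base.
#'
#' @param catalog a \code{\link{region_catalog}}.
#' @param profiles named list (one element per sample, names are sample ids)
#'   of per-sample profile lists as returned by \code{\link{read_depth_file}}.
#' @return An object of class \code{depth_matrix}: a list with \code{catalog},
#'   \code{samples} (in input order) and \code{depths}, a list over region ids
#'   of L_R x n_samples integer matrices.
#' @export
assemble_matrix <- function(catalog, profiles) {
  stopifnot(inherits(catalog, "region_catalog"))
  samples <- names(profiles)
  if (is.null(samples) || any(!nzchar(samples))) {
    stop("profiles must be a named list keyed by sample id")
  }
  if (anyDuplicated(samples)) stop("duplicate sample_id")
  depths <- vector("list", nrow(catalog))
  names(depths) <- catalog$region_id
  for (j in seq_len(nrow(catalog))) {
    rid <- catalog$region_id[j]
    L <- catalog$length[j]
    m <- matrix(0L, nrow = L, ncol = length(samples),
                dimnames = list(NULL, samples))
    for (s in samples) {
      p <- profiles[[s]][[rid]]
      if (!is.null(p)) {
        if (length(p) != L) stop("profile length mismatch for ", rid)
        m[, s] <- p
      }
    }
    depths[[j]] <- m
  }
  structure(list(catalog = catalog, samples = samples, depths = depths),
            class = "depth_matrix")
}

#' Read a per-base depth file against a region catalog
#'
#' Two tab-separated dialects are supported, matching BEDTools output:
#' \describe{
#'   \item{genomecov}{3 columns: chrom, 1-based genomic position, depth
#'     (\code{bedtools genomecov -d} style).}
#'   \item{coverage}{BED region columns followed by a 1-based offset within
#'     the region and the depth (\code{bedtools coverage -d} style); at least
#'     5 columns.}
#' }
#' Positions not listed get depth 0; positions outside the catalog are
#' ignored. Files with a \code{.gz} suffix are decompressed transparently.
#'
#' @param path depth file path.
#' @param catalog a \code{\link{region_catalog}}.
#' @param dialect \code{"auto"} (detect from column count), \code{"genomecov"}
#'   or \code{"coverage"}.
#' @return Named list over region ids of integer depth vectors of length L_R.
#' @export
read_depth_file <- function(path, catalog,
                            dialect = c("auto", "genomecov", "coverage")) {
  dialect <- match.arg(dialect)
  if (endsWith(path, ".gz")) {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    tab[[1L]] <- as.character(tab[[1L]])
    tab <- data.table::as.data.table(tab)
  } else {
    tab <- data.table::fread(path, header = FALSE, sep = "\t",
                             colClasses = list(character = 1))
  }
  if (nrow(tab) == 0L) {
    return(zero_profiles(catalog))
  }
  if (dialect == "auto") {
    dialect <- if (ncol(tab) == 3L) "genomecov" else "coverage"
  }
  if (dialect == "genomecov") {
    if (ncol(tab) != 3L) stop("genomecov dialect requires 3 columns: ", path)
    chrom <- tab[[1L]]
    pos <- tab[[2L]]
    depth <- tab[[3L]]
  } else {
    if (ncol(tab) < 5L) stop("coverage dialect requires >= 5 columns: ", path)
    chrom <- tab[[1L]]
    rstart <- tab[[2L]]
    offset <- tab[[ncol(tab) - 1L]]
    depth <- tab[[ncol(tab)]]
    if (!is.numeric(rstart) || !is.numeric(offset)) {
      stop("non-numeric coordinates in ", path)
    }
    # genomic 1-based position = BED start + 1-based offset
    pos <- rstart + offset
  }
  check_depth_column(depth, path)
  depth <- as.integer(depth)
  pos <- as.integer(pos)
  profiles <- zero_profiles(catalog)
  for (j in seq_len(nrow(catalog))) {
    sel <- chrom == catalog$chrom[j] & pos > catalog$start[j] &
      pos <= catalog$end[j]
    if (!any(sel)) next
    idx <- pos[sel] - catalog$start[j]
    if (anyDuplicated(idx)) {
      stop("duplicate position for region ", catalog$region_id[j],
           " in ", path)
    }
    v <- profiles[[j]]
    v[idx] <- depth[sel]
    profiles[[j]] <- v
  }
  profiles
}

check_depth_column <- function(depth, path) {
  if (!is.numeric(depth)) {
    stop("non-numeric depth column in ", path, " (line ",
         which(is.na(suppressWarnings(as.numeric(depth))))[1L], ")")
  }
  bad <- which(depth < 0 | depth != floor(depth))
  if (length(bad)) {
    stop("negative or non-integer depth in ", path, " at line ", bad[1L])
  }
}

zero_profiles <- function(catalog) {
  p <- lapply(catalog$length, function(L) integer(L))
  names(p) <- catalog$region_id
  p
}

#' Read a directory or list of depth files into a depth matrix
#'
#' @param paths named character vector of depth files (names become sample
#'   ids; unnamed paths use the file name stripped of extensions).
#' @param catalog a \code{\link{region_catalog}}.
#' @param dialect passed to \code{\link{read_depth_file}}.
#' @return A \code{depth_matrix}.
#' @export
read_cohort <- function(paths, catalog, dialect = "auto") {
  ids <- names(paths)
  if (is.null(ids)) ids <- rep("", length(paths))
  auto <- !nzchar(ids)
  ids[auto] <- sub("\\.(tsv|txt|bed)?(\\.gz)?$", "", basename(paths[auto]))
  profiles <- lapply(paths, read_depth_file, catalog = catalog,
                     dialect = dialect)
  names(profiles) <- ids
  assemble_matrix(catalog, profiles)
}

#' Per-sample mean depth over all catalog bases
#'
#' @param matrix a \code{depth_matrix}.
#' @return Named numeric vector: arithmetic mean of per-base depth over every
#'   catalog base, per sample.
#' @export
mean_target_depth <- function(matrix) {
  stopifnot(inherits(matrix, "depth_matrix"))
  totals <- Reduce(`+`, lapply(matrix$depths, colSums))
  totals / sum(matrix$catalog$length)
}

#' Sample-level coverage QC filter
#'
#' Samples whose mean per-base depth over all catalog bases falls below the
#' threshold are removed from the cohort; the returned QC table covers all
#' input samples. The threshold is inclusive: a sample at exactly the
#' threshold passes.
#'
#' @param matrix a \code{depth_matrix}.
#' @param min_mean_depth minimum mean target depth in reads (default 75).
#' @return List with \code{matrix} (filtered \code{depth_matrix}) and
#'   \code{qc} (\code{data.frame}: sample_id, mean_target_depth, pass).
#' @export
qc_filter <- function(matrix, min_mean_depth = 75) {
  stopifnot(inherits(matrix, "depth_matrix"))
  if (length(matrix$samples) == 0L) stop("empty depth matrix")
  md <- mean_target_depth(matrix)
  qc <- data.frame(sample_id = matrix$samples,
                   mean_target_depth = unname(md[matrix$samples]),
                   pass = unname(md[matrix$samples] >= min_mean_depth),
                   stringsAsFactors = FALSE)
  if (!any(qc$pass)) {
    stop("all samples fail the mean-depth QC threshold (",
         min_mean_depth, "X); override min_mean_depth to proceed")
  }
  keep <- qc$sample_id[qc$pass]
  out <- matrix
  out$samples <- keep
  out$depths <- lapply(matrix$depths,
                       function(m) m[, keep, drop = FALSE])
  list(matrix = out, qc = qc)
}

#' Extract one region's depth matrix slice
#'
#' @param matrix a \code{depth_matrix}.
#' @param region_id region identifier.
#' @return Integer matrix, L_R rows (bases) by n_samples columns.
#' @export
region_depths <- function(matrix, region_id) {
  m <- matrix$depths[[region_id]]
  if (is.null(m)) stop("unknown region_id: ", region_id)
  m
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat("depth_matrix:", length(x$depths), "regions x", length(x$samples),
      "samples;", sum(x$catalog$length), "target bases\n")
  invisible(x)
}
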