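#' Generate a synthetic region catalog
#'
#' Genes are laid out on autosomes in order, with exon lengths drawn
#' uniformly from \code{length_range} and fixed intergenic/intronic spacing,
#' so the catalog is deterministic under the seed.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene.
#' @param length_range exon length range in bp (default 120-400, a typical
#'   coding-exon scale).
#' @param n_chroms number of autosomes to spread genes over (default 2).
#' @param seed RNG seed for exon lengths.
#' @return A \code{\link{region_catalog}}.
#' @export
sim_catalog <- function(n_genes = 10, exons_per_gene = 2,
                        length_range = c(120L, 400L), n_chroms = 2L,
                        seed = 1L) {
  set.seed(seed)
  gene <- character()
  chrom <- character()
  start <- integer()
  end <- integer()
  pos <- rep(1000L, n_chroms)
  for (i in seq_len(n_genes)) {
    ch <- ((i - 1L) %% n_chroms) + 1L
    for (e in seq_len(exons_per_gene)) {
      L <- sample(seq(length_range[1L], length_range[2L]), 1L)
      gene <- c(gene, sprintf("G%03d", i))
      chrom <- c(chrom, paste0("chr", ch))
      start <- c(start, pos[ch])
      end <- c(end, pos[ch] + L)
      pos[ch] <- pos[ch] + L + 500L
    }
    pos[ch] <- pos[ch] + 2000L
  }
  region_catalog(gene, chrom, start, end)
}

# smooth raised-cosine bump multiplier profile over a region
bump_multiplier <- function(L, center, width, amplitude) {
  pos <- seq_len(L)
  m <- rep(1, L)
  inside <- abs(pos - center) <= width / 2
  m[inside] <- 1 + (amplitude - 1) *
    0.5 * (1 + cos(2 * pi * (pos[inside] - center) / width))
  m
}

#' Simulate a cohort of per-base exome depths
#'
#' Per sample and base, the expected depth is the base mean scaled by the
#' region's bump, dropout and GC multipliers; integer depths are then either
#' the rounded expectation (\code{noise = "none"}) or drawn from a Poisson or
#' negative binomial (mean mu, variance mu + mu^2/dispersion) with that mean.
#' Each sample uses an RNG substream at \code{seed + sample index}, so output
#' is reproducible byte-for-byte under a fixed seed and config.
#'
#' @param catalog a \code{\link{region_catalog}}.
#' @param n_samples cohort size.
#' @param mean_depth base mean depth in reads (default 50; must be positive).
#' @param noise \code{"none"}, \code{"poisson"} or \code{"nb"}.
#' @param dispersion negative-binomial dispersion k (default 10).
#' @param bumps optional \code{data.frame}: region_id, center (bp within
#'   region, 1-based), width (bp), amplitude (multiplier at the bump apex).
#' @param dropouts optional \code{data.frame}: region_id, start, end
#'   (0-based half-open within the region), multiplier in [0, 1].
#' @param region_gc optional named vector of per-region GC fractions.
#' @param gc_response optional monotone function GC fraction -> depth
#'   multiplier, applied with \code{region_gc}.
#' @param seed integer RNG seed.
#' @return A \code{depth_matrix}.
#' @export
simulate_cohort <- function(catalog, n_samples = 5, mean_depth = 50,
                            noise = c("none", "poisson", "nb"),
                            dispersion = 10, bumps = NULL, dropouts = NULL,
                            region_gc = NULL, gc_response = NULL, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(catalog, "region_catalog"))
  if (mean_depth <= 0) stop("mean_depth must be positive")
  samples <- sprintf("S%02d", seq_len(n_samples))
  mu <- lapply(seq_len(nrow(catalog)), function(j) {
    L <- catalog$length[j]
    rid <- catalog$region_id[j]
    m <- rep(mean_depth, L)
    if (!is.null(bumps)) {
      for (b in which(bumps$region_id == rid)) {
        m <- m * bump_multiplier(L, bumps$center[b], bumps$width[b],
                                 bumps$amplitude[b])
      }
    }
    if (!is.null(dropouts)) {
      for (d in which(dropouts$region_id == rid)) {
        idx <- (dropouts$start[d] + 1L):dropouts$end[d]
        m[idx] <- m[idx] * dropouts$multiplier[d]
      }
    }
    if (!is.null(region_gc) && !is.null(gc_response)) {
      m <- m * gc_response(region_gc[[rid]])
    }
    m
  })
  names(mu) <- catalog$region_id
  depths <- lapply(mu, function(m) {
    matrix(0L, nrow = length(m), ncol = n_samples,
           dimnames = list(NULL, samples))
  })
  for (s in seq_len(n_samples)) {
    set.seed(seed + s)
    for (rid in catalog$region_id) {
      m <- mu[[rid]]
      d <- switch(noise,
                  none = as.integer(round(m)),
                  poisson = stats::rpois(length(m), m),
                  nb = stats::rnbinom(length(m), mu = m, size = dispersion))
      depths[[rid]][, s] <- d
    }
  }
  structure(list(catalog = catalog, samples = samples, depths = depths),
            class = "depth_matrix")
}

#' Write a depth matrix as per-sample depth files
#'
#' @param matrix a \code{depth_matrix}.
#' @param dir output directory (created if needed).
#' @param dialect \code{"genomecov"} (chrom, 1-based position, depth) or
#'   \code{"coverage"} (region BED columns, 1-based offset, depth).
#' @param gzip compress outputs with gzip.
#' @return Named character vector of written paths.
#' @export
write_depth_files <- function(matrix, dir,
                              dialect = c("genomecov", "coverage"),
                              gzip = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(matrix, "depth_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat <- matrix$catalog
  paths <- vapply(matrix$samples, function(s) {
    lines <- unlist(lapply(seq_len(nrow(cat)), function(j) {
      d <- matrix$depths[[j]][, s]
      if (dialect == "genomecov") {
        sprintf("%s\t%d\t%d", cat$chrom[j],
                cat$start[j] + seq_len(cat$length[j]), d)
      } else {
        sprintf("%s\t%d\t%d\t%s\t%d\t%d", cat$chrom[j], cat$start[j],
                cat$end[j], cat$region_id[j], seq_len(cat$length[j]), d)
      }
    }))
    ext <- if (gzip) ".tsv.gz" else ".tsv"
    path <- file.path(dir, paste0(s, ext))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
    path
  }, character(1))
  names(paths) <- matrix$samples
  paths
}

# deterministic sequence of given length and GC fraction (no RNG): G/C and
# A/T bases interleaved as evenly as possible
gc_sequence <- function(L, gc) {
  n_gc <- round(L * gc)
  flags <- floor(seq_len(L) * n_gc / L) - floor((seq_len(L) - 1L) * n_gc / L)
  bases <- ifelse(flags == 1L, c("G", "C"), c("A", "T"))
  paste(bases, collapse = "")
}

#' Write the canonical synthetic fixture suite
#'
#' Emits the named fixtures the test-bench relies on, each a small cohort
#' with known planted structure: \code{uniform} (constant depth; U_E 1, CCS
#' 0), \code{single_bump} and \code{two_bump} (planted coverage peaks),
#' \code{edge_dropout} (a 358 bp region whose coverage collapses after base
#' 200, so CCS = 158/358 without noise), \code{gc_graded} (five regions with
#' GC 0.1-0.9 plus a matching synthetic FASTA), and \code{repeat_trough}
#' (a zero-coverage trough whose extent overlaps a repeat interval in the
#' accompanying BED).
#'
#' @param outdir output directory.
#' @param seed RNG seed used for the noisy fixtures.
#' @return Named list describing each fixture: its catalog, depth-file paths
#'   and any auxiliary files (FASTA, repeats BED).
#' @export
make_fixture_suite <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  cat1 <- region_catalog("UNIF", "chr1", 1000L, 1300L)
  dm <- simulate_cohort(cat1, n_samples = 5, mean_depth = 50, noise = "none",
                        seed = seed)
  out$uniform <- list(
    catalog = cat1,
    depths = write_depth_files(dm, file.path(outdir, "uniform")))
  write_catalog(cat1, file.path(outdir, "uniform", "catalog.bed"))

  cat2 <- region_catalog("BUMP1", "chr1", 2000L, 2300L)
  dm <- simulate_cohort(cat2, n_samples = 5, mean_depth = 50, noise = "none",
                        bumps = data.frame(region_id = "BUMP1|0",
                                           center = 150, width = 120,
                                           amplitude = 3),
                        seed = seed)
  out$single_bump <- list(
    catalog = cat2,
    depths = write_depth_files(dm, file.path(outdir, "single_bump")))

  cat3 <- region_catalog("BUMP2", "chr1", 4000L, 4400L)
  dm <- simulate_cohort(cat3, n_samples = 5, mean_depth = 50, noise = "none",
                        bumps = data.frame(region_id = c("BUMP2|0", "BUMP2|0"),
                                           center = c(100, 300),
                                           width = c(80, 80),
                                           amplitude = c(3, 3)),
                        seed = seed)
  out$two_bump <- list(
    catalog = cat3,
    depths = write_depth_files(dm, file.path(outdir, "two_bump")))

  cat4 <- region_catalog("EDGE", "chr2", 1000L, 1358L)
  dm <- simulate_cohort(cat4, n_samples = 5, mean_depth = 100, noise = "none",
                        dropouts = data.frame(region_id = "EDGE|0",
                                              start = 200L, end = 358L,
                                              multiplier = 0),
                        seed = seed)
  out$edge_dropout <- list(
    catalog = cat4,
    depths = write_depth_files(dm, file.path(outdir, "edge_dropout")))

  gcs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cat5 <- region_catalog(sprintf("GC%02d", round(100 * gcs)), "chr3",
                         seq(1000L, by = 500L, length.out = 5L),
                         seq(1000L, by = 500L, length.out = 5L) + 200L)
  total <- max(cat5$end) + 100L
  seq3 <- rep("A", total)
  for (j in seq_len(nrow(cat5))) {
    s <- strsplit(gc_sequence(cat5$length[j], gcs[j]), "")[[1L]]
    seq3[(cat5$start[j] + 1L):cat5$end[j]] <- s
  }
  fasta <- file.path(outdir, "gc_graded.fa")
  writeLines(c(">chr3", paste(seq3, collapse = "")), fasta)
  gc_mult <- function(gc) ifelse(gc > 0.7 | gc < 0.2, 0.1, 1)
  dm <- simulate_cohort(cat5, n_samples = 5, mean_depth = 50, noise = "none",
                        region_gc = stats::setNames(gcs, cat5$region_id),
                        gc_response = gc_mult, seed = seed)
  out$gc_graded <- list(
    catalog = cat5, fasta = fasta,
    depths = write_depth_files(dm, file.path(outdir, "gc_graded")))

  cat6 <- region_catalog("RPT", "chr4", 1000L, 1300L)
  dm <- simulate_cohort(cat6, n_samples = 5, mean_depth = 50, noise = "none",
                        dropouts = data.frame(region_id = "RPT|0",
                                              start = 100L, end = 180L,
                                              multiplier = 0),
                        seed = seed)
  repeats <- file.path(outdir, "repeat_trough_repeats.bed")
  writeLines("chr4\t1120\t1160\tSINE/Alu\t0\t+", repeats)
  out$repeat_trough <- list(
    catalog = cat6, repeats = repeats,
    depths = write_depth_files(dm, file.path(outdir, "repeat_trough")))

  out
}
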