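test_that("overlapping exons of one gene merge into maximal disjoint intervals", {
  exons <- data.frame(gene = "G", chrom = "chr1",
                      start = c(10L, 40L), end = c(50L, 80L))
  cat <- merge_transcript_exons(exons)
  expect_equal(nrow(cat), 1L)
  expect_equal(cat$start, 10L)
  expect_equal(cat$end, 80L)

  disjoint <- data.frame(gene = "G", chrom = "chr1",
                         start = c(10L, 30L), end = c(20L, 40L))
  cat2 <- merge_transcript_exons(disjoint)
  expect_equal(cat2$exon_index, c(0L, 1L))
  expect_equal(cat2$start, c(10L, 30L))

  triple <- data.frame(gene = "G", chrom = "chr1",
                       start = c(10L, 20L, 55L), end = c(60L, 30L, 70L))
  cat3 <- merge_transcript_exons(triple)
  # brute-force union over integer positions
  bases <- sort(unique(unlist(Map(seq, triple$start, triple$end - 1L))))
  expect_equal(cat3$start, 10L)
  expect_equal(cat3$end, 70L)
  expect_equal(sum(cat3$length), length(bases))
})

test_that("merged base counts match brute-force position-set union", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    start <- sample(0:200, n)
    len <- sample(5:60, n, replace = TRUE)
    exons <- data.frame(gene = "G", chrom = "chr5", start = start,
                        end = start + len)
    cat <- merge_transcript_exons(exons)
    truth <- sort(unique(unlist(Map(seq, exons$start, exons$end - 1L))))
    got <- sort(unlist(Map(seq, cat$start, cat$end - 1L)))
    expect_equal(got, truth)
  }
})

test_that("merging is idempotent and rejects cross-chromosome genes", {
  exons <- data.frame(gene = c("A", "A", "B"), chrom = "chr2",
                      start = c(0L, 5L, 100L), end = c(10L, 20L, 150L))
  cat <- merge_transcript_exons(exons)
  again <- merge_transcript_exons(
    data.frame(gene = cat$gene, chrom = cat$chrom, start = cat$start,
               end = cat$end))
  expect_equal(again$start, cat$start)
  expect_equal(again$end, cat$end)
  expect_equal(again$region_id, cat$region_id)

  bad <- data.frame(gene = "X", chrom = c("chr1", "chr2"),
                    start = c(0L, 0L), end = c(10L, 10L))
  expect_warning(out <- merge_transcript_exons(bad), "multiple chromosomes")
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(merge_transcript_exons(exons[0, ])), 0L)
})

test_that("target intersection restricts, fragments, and drops non-autosomes", {
  cat <- region_catalog("G", "chr1", 10L, 80L)
  t_super <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  out <- intersect_targets(cat, t_super)
  expect_equal(out$start, 10L)
  expect_equal(out$end, 80L)

  t_frag <- data.frame(chrom = "chr1", start = c(10L, 50L), end = c(30L, 80L))
  out2 <- intersect_targets(cat, t_frag)
  expect_equal(out2$start, c(10L, 50L))
  expect_equal(out2$end, c(30L, 80L))
  expect_equal(out2$exon_index, c(0L, 1L))

  catx <- region_catalog(c("G", "H"), c("chr1", "chrX"), c(10L, 10L),
                         c(80L, 80L))
  outx <- intersect_targets(catx, t_super)
  expect_false("H" %in% outx$gene)

  expect_warning(empty <- intersect_targets(
    cat, data.frame(chrom = "chr9", start = 0L, end = 10L)), "no overlap")
  expect_equal(nrow(empty), 0L)
})

test_that("intersection base set equals brute-force set intersection", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(1:4, 1)
    s <- sample(0:150, n)
    cat <- merge_transcript_exons(
      data.frame(gene = "G", chrom = "chr3", start = s, end = s + sample(10:50, n, replace = TRUE)))
    m <- sample(1:4, 1)
    ts <- sample(0:180, m)
    targets <- data.frame(chrom = "chr3", start = ts,
                          end = ts + sample(5:40, m, replace = TRUE))
    out <- suppressWarnings(intersect_targets(cat, targets))
    cat_bases <- unlist(Map(seq, cat$start, cat$end - 1L))
    t_bases <- unique(unlist(Map(seq, targets$start, targets$end - 1L)))
    truth <- sort(intersect(cat_bases, t_bases))
    got <- if (nrow(out)) sort(unlist(Map(seq, out$start, out$end - 1L))) else integer()
    expect_equal(got, truth)
  }
})

test_that("BED and catalog IO round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t9\t20", path)
  one <- read_bed(path)
  expect_equal(one$start, 9L)
  expect_equal(one$end, 20L)

  writeLines(c("chr1\t9\t20\ta\t0\t+", "chr2\t0\t5\tb\t0\t-"), path)
  bed <- read_bed(path)
  expect_equal(bed$chrom, c("chr1", "chr2"))
  expect_equal(bed$start, c(9L, 0L))
  expect_equal(bed$end, c(20L, 5L))

  writeLines("chr1\t20\t9", path)
  expect_error(read_bed(path), "start >= end")
  writeLines("chr1\t9", path)
  expect_error(read_bed(path), "fewer than 3")

  cat <- region_catalog(c("A", "A", "B"), c("chr1", "chr1", "chr2"),
                        c(0L, 50L, 10L), c(10L, 80L, 30L))
  out <- withr::local_tempfile(fileext = ".bed")
  write_catalog(cat, out)
  back <- read_catalog(out)
  expect_equal(back$region_id, cat$region_id)
  expect_equal(back$start, cat$start)
  expect_equal(back$end, cat$end)
  expect_equal(back$gene, cat$gene)
})

test_that("refFlat-style transcript tables parse into per-exon rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1\tNM_1\tchr1\t+\t10,40\t50,80",
               "G1\tNM_2\tchr1\t+\t45\t90"), path)
  ex <- read_transcript_table(path)
  expect_equal(nrow(ex), 3L)
  cat <- merge_transcript_exons(ex)
  expect_equal(cat$start, 10L)
  expect_equal(cat$end, 90L)

  writeLines("G1\tNM_1\tchr1\t+\t50\t10", path)
  expect_error(read_transcript_table(path), "line 1")
})
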