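test_that("median profile uses the position-wise midpoint convention", {
  one <- toy_matrix(c(3, 7, 2))
  expect_equal(median_profile(one), c(3, 7, 2))
  three <- toy_matrix(c(5, 1), c(10, 2), c(100, 3))
  expect_equal(median_profile(three), c(10, 2))
  four <- toy_matrix(0, 10, 20, 30)
  expect_equal(median_profile(four), 15)
})

test_that("lowess smoothing preserves constants and straight lines", {
  const <- rep(20, 50)
  expect_equal(smooth_profile(const, 0.03), const)
  line <- 3 + 0.5 * seq_len(80)
  expect_equal(smooth_profile(line, 0.1), line, tolerance = 1e-9)
  expect_error(smooth_profile(5), "at least 2")
  expect_error(smooth_profile(1:10, span = 0), "span")
})

test_that("lowess matches an independent reference on a noisy sinusoid", {
  set.seed(21)
  n <- 500
  y <- 50 + 20 * sin(seq(0, 6 * pi, length.out = n)) + rnorm(n, sd = 4)
  expect_equal(smooth_profile(y, 0.1), lowess_reference(y, 0.1),
               tolerance = 1e-8)
  expect_equal(smooth_profile(y, 0.03), lowess_reference(y, 0.03),
               tolerance = 1e-8)
})

test_that("extremum detection handles modes, plateaus, and flat curves", {
  ex <- detect_extrema(c(1, 2, 3, 2, 1))
  expect_equal(ex$peaks, 3L)
  expect_equal(ex$troughs, c(1L, 5L))
  expect_equal(detect_extrema(rep(5, 5))$peaks, integer())
  expect_equal(detect_extrema(rep(5, 5))$troughs, integer())
  # plateau collapses to its center
  expect_equal(detect_extrema(c(1, 2, 2, 2, 1))$peaks, 3L)
  # endpoints are never peaks
  expect_equal(detect_extrema(c(3, 2, 1))$peaks, integer())
  expect_equal(detect_extrema(c(3, 2, 1))$troughs, 3L)
})

test_that("extremum detection equals the exhaustive neighbor-scan oracle", {
  # every curve up to length 9 over depth values {0, 1, 2}; the acceptance
  # suite extends the same sweep to length 12
  for (L in 3:9) {
    grid <- as.matrix(expand.grid(rep(list(0:2), L)))
    for (r in seq_len(nrow(grid))) {
      v <- as.numeric(grid[r, ])
      got <- detect_extrema(v)
      want <- extrema_brute(v)
      if (!identical(got, want)) {
        fail(sprintf("extrema mismatch on curve [%s]",
                     paste(v, collapse = ",")))
      }
    }
  }
  succeed()
})

test_that("peaks alternate with troughs (exactly one trough between peaks)", {
  set.seed(31)
  for (rep in 1:50) {
    v <- round(stats::filter(rpois(60, 20), rep(1 / 5, 5), sides = 2), 2)
    v <- v[!is.na(v)]
    ex <- detect_extrema(v)
    if (length(ex$peaks) >= 2L) {
      for (i in seq_len(length(ex$peaks) - 1L)) {
        between <- ex$troughs[ex$troughs > ex$peaks[i] &
                                ex$troughs < ex$peaks[i + 1L]]
        expect_length(between, 1L)
      }
    }
  }
})

test_that("peak geometry measures H, B, W against flanking troughs", {
  v <- c(1, 2, 3, 2, 1)
  pg <- peak_geometry(v, detect_extrema(v))
  expect_equal(pg$H, 3)
  expect_equal(pg$B, 1)
  expect_equal(pg$W, 4)
  # symmetric two-peak curve: identical geometry for both peaks
  v2 <- c(1, 3, 1, 3, 1)
  pg2 <- peak_geometry(v2, detect_extrema(v2))
  expect_equal(nrow(pg2), 2L)
  expect_equal(pg2$H, c(3, 3))
  expect_equal(pg2$B, c(1, 1))
  expect_equal(pg2$W, c(2, 2))
  # zero-coverage flanks floor B at the epsilon
  v3 <- c(0, 5, 0)
  pg3 <- peak_geometry(v3, detect_extrema(v3))
  expect_equal(pg3$B, 0.5)
  expect_equal(pg3$H, 5)
})

test_that("the unevenness formula evaluates peak geometry", {
  expect_equal(ue_score(peak_geometry(rep(1, 5), detect_extrema(rep(1, 5))),
                        5)$ue, 1)
  one <- data.frame(apex_pos = 150L, H = 100, B = 50, W = 150,
                    left_trough_pos = 75L, right_trough_pos = 225L)
  expect_equal(ue_score(one, 300)$ue, 4)
  two <- rbind(one, one)
  expect_equal(ue_score(two, 300)$ue, 8)
})

test_that("uniform cohorts score exactly 1 and planted bumps score above 1", {
  cat <- region_catalog("U", "chr1", 0L, 300L)
  dm <- simulate_cohort(cat, n_samples = 5, mean_depth = 50, noise = "none",
                        seed = 1)
  res <- ue_for_matrix(dm)
  expect_equal(res$ue, 1)
  expect_equal(res$n_peaks, 0L)

  dmb <- simulate_cohort(cat, n_samples = 5, mean_depth = 50, noise = "none",
                         bumps = data.frame(region_id = "U|0", center = 150,
                                            width = 120, amplitude = 3),
                         seed = 1)
  expect_gt(ue_for_matrix(dmb)$ue, 1)
})

test_that("ue is scale invariant and increases under zero-coverage dropout", {
  cat <- region_catalog("R", "chr1", 0L, 300L)
  dm <- simulate_cohort(cat, n_samples = 5, mean_depth = 50, noise = "none",
                        bumps = data.frame(region_id = "R|0", center = 100,
                                           width = 80, amplitude = 2.5),
                        seed = 1)
  m <- region_depths(dm, "R|0")
  ue1 <- ue_region(m)$ue
  ue2 <- ue_region(2L * m)$ue
  expect_equal(ue2, ue1, tolerance = 1e-12)

  # a zero-coverage trough in a formerly uniform region raises ue above 1
  dmu <- simulate_cohort(cat, n_samples = 5, mean_depth = 50, noise = "none",
                         seed = 1)
  mu <- region_depths(dmu, "R|0")
  base_ue <- ue_region(mu)$ue
  mu[140:160, ] <- 0L
  expect_gt(ue_region(mu)$ue, base_ue)
})

test_that("ue stays >= 1 on random noisy cohorts", {
  set.seed(77)
  for (rep in 1:15) {
    m <- matrix(rnbinom(200 * 4, mu = 40, size = 5), ncol = 4)
    expect_gte(ue_region(m)$ue, 1)
  }
})

test_that("short regions are skipped for ue with a warning", {
  cat <- region_catalog(c("A", "B"), "chr1", c(0L, 100L), c(3L, 400L))
  m1 <- matrix(50L, 3, 2, dimnames = list(NULL, c("a", "b")))
  m2 <- matrix(50L, 300, 2, dimnames = list(NULL, c("a", "b")))
  dm <- structure(list(catalog = cat, samples = c("a", "b"),
                       depths = list("A|0" = m1, "B|0" = m2)),
                  class = "depth_matrix")
  expect_warning(res <- ue_for_matrix(dm), "skipped")
  expect_equal(res$region_id, "B|0")
})
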