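# stepwise-window scan: Pi / GC / gap, correlations, hotspot ranking

test_that("sliding windows enumerate full windows only", {
  w <- sliding_windows(2000, 600, 200)
  expect_equal(nrow(w), 8L)
  expect_equal(unname(w[1, ]), c(0L, 600L))
  expect_equal(unname(w[8, ]), c(1400L, 2000L))
  expect_equal(nrow(sliding_windows(600, 600, 200)), 1L)
  expect_equal(nrow(sliding_windows(599, 600, 200)), 0L)
  expect_error(sliding_windows(1000, 0, 200))
})

test_that("window_pi matches the hand-computed three-row example", {
  aln <- aln_from("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT")
  res <- window_pi(aln, c(0, 10))
  expect_equal(res$pi, (0.1 + 0.2 + 0.1) / 3, tolerance = 1e-12)
  expect_equal(res$n_pairs_used, 3L)
  # identical rows -> zero
  same <- aln_from("ACGTACGT", "ACGTACGT")
  expect_equal(window_pi(same, c(0, 8))$pi, 0)
})

test_that("pi is NA (not zero) when no pair has comparable sites", {
  aln <- aln_from("----NNNN", "NNNN----", "--------")
  expect_true(is.na(window_pi(aln, c(0, 8))$pi))
  expect_equal(window_pi(aln, c(0, 8))$n_pairs_used, 0L)
})

test_that("window_pi equals the brute-force oracle on random alignments", {
  set.seed(11)
  for (rep in 1:25) {
    aln <- random_alignment(sample(2:8, 1), sample(20:120, 1),
                            gap_prob = runif(1, 0, 0.3),
                            n_prob = runif(1, 0, 0.2))
    expect_equal(window_pi(aln, c(0, aln_length(aln)))$pi, brute_pi(aln),
                 tolerance = 1e-12)
  }
})

test_that("window_gc and window_gap follow their definitions", {
  aln <- aln_from("GCGC", "GCGC")
  expect_equal(window_gc(aln, c(0, 4)), 1)
  aln2 <- aln_from("ATGC", "ATGC")
  expect_equal(window_gc(aln2, c(0, 4)), 0.5)
  aln3 <- aln_from("A-GC", "A--C")
  expect_equal(window_gap(aln3, c(0, 4)), 3 / 8)
  expect_equal(window_gap(aln2, c(0, 4)), 0)
  # N counts as a base cell for gap, is excluded from GC's denominator
  aln4 <- aln_from("AN-C", "ANNC")
  expect_equal(window_gap(aln4, c(0, 4)), 1 / 8)
  expect_equal(window_gc(aln4, c(0, 4)), 2 / 4)
  # one row entirely gaps in a 5-row window
  aln5 <- aln_from("ACGT", "ACGT", "ACGT", "ACGT", "----")
  expect_equal(window_gap(aln5, c(0, 4)), 0.2)
})

test_that("scan agrees with single-window statistics and is order-stable", {
  set.seed(4)
  aln <- random_alignment(5, 900, gap_prob = 0.12, n_prob = 0.05)
  prof <- scan_windows(aln, 300, 100)
  expect_equal(prof$window_start, seq(0, 600, by = 100))
  for (i in seq_len(nrow(prof))) {
    w <- c(prof$window_start[i], prof$window_end[i])
    expect_equal(prof$pi[i], window_pi(aln, w)$pi, tolerance = 1e-12)
    expect_equal(prof$gc[i], window_gc(aln, w), tolerance = 1e-12)
    expect_equal(prof$gap[i], window_gap(aln, w), tolerance = 1e-12)
  }
})

test_that("pi, gc and gap are invariant under row reordering", {
  set.seed(5)
  aln <- random_alignment(6, 400)
  perm <- sample(6)
  aln2 <- alignment_matrix(stats::setNames(
    apply(aln$mat[perm, ], 1, paste, collapse = ""), aln$names[perm]))
  p1 <- scan_windows(aln, 200, 200)
  p2 <- scan_windows(aln2, 200, 200)
  expect_equal(p1$pi, p2$pi)
  expect_equal(p1$gc, p2$gc)
  expect_equal(p1$gap, p2$gap)
})

test_that("adding substitutions to one row never decreases pi", {
  set.seed(6)
  base <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  aln <- aln_from(a = base, b = base, d = base)
  p0 <- scan_windows(aln, 200, 200)$pi
  v <- strsplit(base, "")[[1]]
  idx <- sample(600, 30)
  v[idx] <- vapply(v[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  aln2 <- aln_from(a = base, b = base, d = paste(v, collapse = ""))
  p1 <- scan_windows(aln2, 200, 200)$pi
  expect_true(all(p1 >= p0 - 1e-12))
  expect_true(any(p1 > p0))
})

test_that("doubling the step keeps exactly the even-indexed windows", {
  set.seed(8)
  aln <- random_alignment(4, 3000)
  p200 <- scan_windows(aln, 600, 200)
  p400 <- scan_windows(aln, 600, 400)
  sel <- seq(1, nrow(p200), by = 2)[seq_len(nrow(p400))]
  expect_equal(p400$window_start, p200$window_start[sel])
  expect_equal(p400$pi, p200$pi[sel])
})

test_that("correlation matches the closed-form OLS oracle", {
  x <- 0:4
  y <- 2 * x + 1 + c(0.1, -0.2, 0.05, 0.15, -0.1)
  # build windows whose sqrt(pi) equals y and gc equals x
  prof <- data.frame(window_start = 0:4, window_end = 1:5,
                     pi = y^2, gc = x, gap = 0, n_pairs_used = 3L)
  res <- correlate_windows(prof, "gc")
  oracle <- ols_oracle(x, y)
  expect_equal(res$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(res$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(res$r, oracle$r, tolerance = 1e-10)
  expect_equal(res$n_windows, 5L)
})

test_that("exactly collinear points give |r| = 1 and a vanishing p-value", {
  prof <- data.frame(window_start = 0:4, window_end = 1:5,
                     pi = (0.1 * (1:5))^2, gc = 1:5, gap = 0,
                     n_pairs_used = 3L)
  res <- suppressWarnings(correlate_windows(prof, "gc"))
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-12)
  expect_error(correlate_windows(prof[1:2, ], "gc"), "3")
})

test_that("windows with undefined pi are excluded from the regression", {
  prof <- data.frame(window_start = 0:5, window_end = 1:6,
                     pi = c(0.01, 0.02, NA, 0.03, 0.01, 0.04),
                     gc = c(1:5, 6) / 10, gap = 0, n_pairs_used = 3L)
  res <- correlate_windows(prof, "gc")
  expect_equal(res$n_windows, 5L)
  expect_equal(res$n_excluded, 1L)
})

test_that("hotspot runs merge overlapping windows and rank by peak pi", {
  prof <- data.frame(
    window_start = c(0, 200, 400, 1200, 2000),
    window_end = c(600, 800, 1000, 1800, 2600),
    pi = c(0.05, 0.04, 0.01, 0.06, 0.02),
    gc = 0.4, gap = 0, n_pairs_used = 10L)
  hs <- rank_hotspots(prof, threshold = 0.03)
  expect_equal(nrow(hs), 2L)
  expect_equal(hs$start[1], 1200)        # highest peak first
  expect_equal(hs$end[2], 800)           # two overlapping windows merged
  expect_equal(hs$n_windows[2], 2L)
  expect_equal(nrow(rank_hotspots(prof, threshold = 0.99)), 0L)
  expect_equal(nrow(rank_hotspots(prof[0, ], threshold = 0.03)), 0L)
})

test_that("hotspots are labeled with overlapping named regions", {
  prof <- data.frame(window_start = 0, window_end = 600, pi = 0.05,
                     gc = 0.4, gap = 0, n_pairs_used = 10L)
  regions <- data.frame(name = c("rps16-trnQ", "matK"),
                        kind = c("IGS", "exon"),
                        start = c(100, 700), end = c(500, 1200))
  hs <- rank_hotspots(prof, regions, threshold = 0.03)
  expect_equal(hs$regions, "rps16-trnQ")
})
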