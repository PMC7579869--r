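flat_map <- function(pos, chrom_length_bp) {
  marker_map(paste0("m", seq_along(pos)), "1", pos,
             chrom_length_bp = chrom_length_bp)
}

test_that("chromosome fractions follow the midpoint-interval convention", {
  # all markers one ancestry -> fraction 1 with edge extension
  map <- flat_map(c(100L, 200L, 300L), 400L)
  f <- chromosome_ancestry_fraction(rep("EUR", 3), map)
  expect_equal(unname(f), c(1, 0, 0))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # 3 equally spaced markers (EUR, AFR, EUR) on a chromosome exactly spanning
  # them: AFR owns the interval between the two midpoints
  map2 <- flat_map(c(100L, 200L, 300L), 300L)
  f2 <- chromosome_ancestry_fraction(c("EUR", "AFR", "EUR"), map2)
  expect_equal(f2[["AFR"]], 100 / 300)   # [150, 250] / 300, hand-computed
  expect_equal(f2[["EUR"]], 200 / 300)
  expect_equal(sum(f2), 1, tolerance = 1e-12)
})

test_that("fractions are invariant to marker storage order", {
  set.seed(31)
  pos <- sort(sample.int(1e6, 40))
  map <- flat_map(pos, 1.2e6)
  lab <- sample(ANCESTRY_LABELS, 40, replace = TRUE)
  f <- chromosome_ancestry_fraction(lab, map)
  perm <- sample(40)
  # positions fixed: permuting storage means permuting both map rows and track,
  # then re-sorting by position inside marker_map
  ord <- order(pos[perm])
  map_p <- flat_map(pos[perm][ord], 1.2e6)
  f_p <- chromosome_ancestry_fraction(lab[perm][ord], map_p)
  expect_equal(f, f_p)
})

test_that("per-marker fractions count labels and sum to one", {
  map <- flat_map(c(10L, 20L), 30L)
  labels <- rbind(c("EUR", "EUR"), c("EUR", "EUR"), c("AFR", "EUR"),
                  c("AFR", "AMR"))
  tracks <- ancestry_tracks(map, labels, c("S1", "S1", "S2", "S2"),
                            carrier = c(TRUE, TRUE, FALSE, FALSE))
  pm <- per_marker_fraction(tracks, subset = rep(TRUE, 4))
  expect_equal(unname(pm[, 1L]), c(0.5, 0, 0.5))       # EUR, AMR, AFR at m1
  expect_equal(unname(pm[, 2L]), c(0.75, 0.25, 0))
  expect_equal(unname(pm["EUR", ]), c(0.5, 0.75))
  set.seed(32)
  big <- simulate_ancestry_tracks(20L, flat_map(sort(sample.int(1e6, 50)), 1.1e6),
                                  c(0.5, 0.3, 0.2))
  pm2 <- per_marker_fraction(big, subset = rep(TRUE, 20))
  expect_true(all(abs(colSums(pm2) - 1) < 1e-12))
  expect_error(per_marker_fraction(big, subset = rep(FALSE, 20)), "empty")
})

test_that("midpoint weighting ties per-marker and chromosome fractions together", {
  set.seed(33)
  map <- flat_map(sort(sample.int(2e6, 60)), 2.2e6)
  tracks <- simulate_ancestry_tracks(30L, map, c(0.6, 0.25, 0.15),
                                     carrier = rep(c(TRUE, FALSE), c(10, 20)))
  subset <- rep(TRUE, 30L)
  pm <- per_marker_fraction(tracks, subset)
  w <- foundertrace:::midpoint_weights(map)
  weighted <- as.vector(pm %*% w) / sum(w)
  mean_chrom <- rowMeans(vapply(seq_len(30L), function(i) {
    chromosome_ancestry_fraction(tracks$labels[i, ], map)
  }, numeric(3L)))
  expect_equal(weighted, unname(mean_chrom), tolerance = 1e-12)
})

test_that("the t test matches the closed form and its symmetries", {
  tt <- two_sample_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-12)  # pooled var = 1
  expect_equal(tt$df, 4)
  # identical samples -> t = 0, p = 1 (zero-variance degenerate case)
  same <- two_sample_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(lim <- two_sample_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(lim$p, 0)
  # swapping groups negates t and preserves p
  x <- rnorm(10); y <- rnorm(12, 0.5)
  a <- two_sample_t_test(x, y)
  b <- two_sample_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # Welch fallback reaches t.test(var.equal = FALSE)
  w <- two_sample_t_test(x, y, equal_variance = FALSE)
  ref <- t.test(x, y)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_error(two_sample_t_test(1, c(1, 2)), "n >= 2")
})

test_that("carrier-ancestry comparison reports group summaries and the test", {
  set.seed(34)
  # chromosome-scale map (~80 cM) so each haplotype averages several tracts
  map <- flat_map(sort(sample.int(8e7, 200)), 81195210L)
  t_car <- simulate_ancestry_tracks(40L, map, c(0.8, 0.15, 0.05))
  t_ctl <- simulate_ancestry_tracks(200L, map, c(0.6, 0.3, 0.1))
  tracks <- ancestry_tracks(map, rbind(t_car$labels, t_ctl$labels),
                            c(paste0("CA", rep(1:20, each = 2)),
                              paste0("CO", rep(1:100, each = 2))),
                            carrier = rep(c(TRUE, FALSE), c(40, 200)))
  cmp <- compare_carrier_ancestry(tracks, "EUR")
  expect_equal(cmp$n_carrier, 20L)
  expect_equal(cmp$n_control, 100L)
  expect_gt(cmp$carrier_mean, cmp$control_mean)
  expect_lt(cmp$p, 0.05)
  expect_output(print(cmp), "Student")
  # single-ancestry world: both groups at 1.0, t = 0
  mono <- ancestry_tracks(map, matrix("EUR", 8, 200),
                          rep(c("A", "B", "C", "D"), each = 2),
                          carrier = rep(c(TRUE, FALSE), each = 4))
  cmp0 <- compare_carrier_ancestry(mono, "EUR")
  expect_equal(cmp0$carrier_mean, 1)
  expect_equal(cmp0$control_mean, 1)
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p, 1)
})

test_that("ancestry tracks round-trip through TSV", {
  set.seed(35)
  map <- flat_map(sort(sample.int(5e5, 25)), 6e5)
  tracks <- simulate_ancestry_tracks(6L, map, c(0.5, 0.3, 0.2),
                                     carrier = rep(c(TRUE, FALSE), c(2, 4)))
  tmp <- tempfile(fileext = ".tsv")
  write_ancestry_tracks(tracks, tmp)
  back <- read_ancestry_tracks(tmp, map, tracks$sample_of_haplotype,
                               tracks$carrier)
  expect_identical(unname(back$labels), unname(tracks$labels))
})
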