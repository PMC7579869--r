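# panel whose carriers are all identical within [41223094, 41487451] and
# guaranteed to disagree at the next marker on each side, reproducing the
# published core-window geometry
core_fixture_panel <- function() {
  pos <- c(41100000L, 41223094L, 41300000L, 41400000L, 41487451L, 41600000L)
  map <- marker_map(paste0("m", 1:6), "17", pos)
  founder <- c(1L, 0L, 1L, 1L, 0L, 1L)
  a <- matrix(rep(founder, each = 4L), nrow = 4L)
  a[1L, 1L] <- 0L  # mismatch just left of the core
  a[2L, 6L] <- 0L  # mismatch just right of the core
  haplotype_panel(map, a, rep(c("S1", "S2"), each = 2L),
                  carries_mutation = TRUE)
}

test_that("core detection reproduces the published window geometry", {
  panel <- core_fixture_panel()
  focal <- focal_mutation("17", 41244000L)
  core <- find_core_haplotype(panel, focal)
  expect_identical(core$start_bp, 41223094L)
  expect_identical(core$end_bp, 41487451L)
  expect_identical(core$length_bp, 264357L)
  expect_identical(format_kb(core$length_bp), "264.4 kb")
  expect_identical(core$left_marker_id, "m2")
  expect_identical(core$right_marker_id, "m5")
  expect_equal(unname(core$consensus_alleles), c(0L, 1L, 1L, 0L))
})

test_that("identical haplotypes give a core spanning the whole map", {
  map <- marker_map(paste0("m", 1:5), "17",
                    seq(41e6, by = 1e5, length.out = 5))
  a <- matrix(rep(c(0L, 1L, 1L, 0L, 1L), each = 4L), nrow = 4L)
  panel <- haplotype_panel(map, a, rep(c("S1", "S2"), each = 2L),
                           carries_mutation = TRUE)
  core <- find_core_haplotype(panel, focal_mutation("17", 41200000L))
  expect_identical(core$start_bp, map$pos_bp[1L])
  expect_identical(core$end_bp, map$pos_bp[5L])
})

test_that("core boundaries equal the brute-force scan on random panels", {
  for (seed in 1:40) {
    panel <- build_random_panel(n_hap = sample(2:10, 1), n_markers = sample(5:50, 1),
                                miss_rate = 0.15, seed = seed)
    focal <- random_focal(panel$map)
    for (policy in c("ignore", "mismatch")) {
      for (mm in 0:1) {
        ref <- oracle_core(panel, focal, policy, mm)
        got <- suppressWarnings(
          find_core_haplotype(panel, focal, missing_policy = policy,
                              max_mismatch_haps = mm))
        expect_identical(got$start_bp, as.integer(ref$start_bp),
                         info = sprintf("seed %d policy %s mm %d", seed, policy, mm))
        expect_identical(got$end_bp, as.integer(ref$end_bp))
      }
    }
  }
})

test_that("pairwise segments: identical, minimal, and oracle-equivalent cases", {
  map <- marker_map(paste0("m", 1:6), "17",
                    seq(41e6, by = 1e5, length.out = 6))
  focal <- focal_mutation("17", 41250000L)  # between m3 and m4
  a <- rbind(c(0L, 1L, 0L, 1L, 0L, 1L),
             c(1L, 0L, 0L, 1L, 1L, 0L))  # agree only at flanking m3, m4
  a <- rbind(a, a)
  panel <- haplotype_panel(map, a, rep(c("S1", "S2"), each = 2L),
                           carries_mutation = TRUE)
  ids <- haplotype_ids(panel)
  seg <- pairwise_shared_segment(panel, focal, ids[1L], ids[2L])
  expect_identical(seg$start_bp, map$pos_bp[3L])
  expect_identical(seg$end_bp, map$pos_bp[4L])
  # identical haplotype ids: whole map with warning
  expect_warning(whole <- pairwise_shared_segment(panel, focal, ids[1L], ids[1L]),
                 "whole map")
  expect_identical(whole$start_bp, map$pos_bp[1L])
  expect_identical(whole$end_bp, map$pos_bp[6L])
  # identical haplotypes (different ids)
  seg13 <- pairwise_shared_segment(panel, focal, ids[1L], ids[3L])
  expect_identical(seg13$start_bp, map$pos_bp[1L])
  expect_identical(seg13$end_bp, map$pos_bp[6L])
})

test_that("pairwise segments equal the brute-force extension oracle", {
  for (seed in 41:70) {
    panel <- build_random_panel(n_hap = 4L, n_markers = sample(8:40, 1),
                                miss_rate = 0.1, seed = seed)
    focal <- random_focal(panel$map)
    ids <- haplotype_ids(panel)
    for (mm in 0:2) {
      ref <- oracle_segment(panel, focal, ids[1L], ids[2L], max_mm = mm)
      got <- pairwise_shared_segment(panel, focal, ids[1L], ids[2L],
                                     max_mismatches = mm)
      expect_identical(got$start_bp, as.integer(ref$start_bp),
                       info = sprintf("seed %d mm %d", seed, mm))
      expect_identical(got$end_bp, as.integer(ref$end_bp))
    }
  }
})

test_that("the core interval is contained in every pairwise shared segment", {
  for (seed in 1:10) {
    cfg <- sim_config(n_markers = 300L, region_bp = c(40e6, 43e6),
                      n_carriers = 8L, n_controls = 0L, seed = seed)
    sim <- simulate_carrier_panel(cfg)
    core <- suppressWarnings(find_core_haplotype(sim$panel, cfg$focal))
    segs <- all_shared_segments(sim$panel, cfg$focal)
    expect_true(all(segs$start_bp <= core$start_bp))
    expect_true(all(segs$end_bp >= core$end_bp))
  }
})

test_that("adding a haplotype can only shrink or preserve the core", {
  for (seed in 11:20) {
    panel <- build_random_panel(n_hap = 8L, n_markers = 40L, miss_rate = 0.05,
                                seed = seed)
    focal <- random_focal(panel$map)
    sub6 <- panel
    sub6$alleles <- panel$alleles[1:6, ]
    sub6$sample_of_haplotype <- panel$sample_of_haplotype[1:6]
    sub6$carries_mutation <- panel$carries_mutation[1:6]
    core6 <- suppressWarnings(find_core_haplotype(sub6, focal))
    core8 <- suppressWarnings(find_core_haplotype(panel, focal))
    expect_true(core8$start_bp >= core6$start_bp)
    expect_true(core8$end_bp <= core6$end_bp)
  }
})

test_that("on error-free panels the core equals the intersection of truth intervals", {
  for (seed in 1:8) {
    cfg <- sim_config(n_markers = 500L, region_bp = c(39e6, 44e6),
                      n_carriers = 12L, n_controls = 0L, seed = seed,
                      genotyping_error_rate = 0, missing_rate = 0)
    sim <- simulate_carrier_panel(cfg)
    # intersection of the true retained marker index sets
    common <- Reduce(intersect, sim$truth$retained_marker_idx)
    core <- suppressWarnings(find_core_haplotype(sim$panel, cfg$focal))
    map <- sim$panel$map
    # the detected core may extend past the truth interval by chance matches of
    # background alleles, never fall short of it
    expect_true(core$start_bp <= map$pos_bp[min(common)])
    expect_true(core$end_bp >= map$pos_bp[max(common)])
    # and all carriers are identical on the detected core
    idx <- which(map$pos_bp >= core$start_bp & map$pos_bp <= core$end_bp)
    carriers <- sim$panel$alleles[sim$panel$carries_mutation, idx]
    expect_true(all(apply(carriers, 2L, function(z) length(unique(z)) == 1L)))
  }
})

test_that("carrier-haplotype selection recovers the mutation-bearing phase", {
  for (seed in 30:34) {
    cfg <- sim_config(n_markers = 400L, n_carriers = 15L, n_controls = 0L,
                      seed = seed, genotyping_error_rate = 0, missing_rate = 0)
    sim <- simulate_carrier_panel(cfg)
    panel <- sim$panel
    truth_flags <- panel$carries_mutation
    panel$carries_mutation <- rep(FALSE, nrow(panel$alleles))
    carriers <- unique(panel$sample_of_haplotype)
    got <- assign_carrier_haplotypes(panel, carriers, cfg$focal,
                                     window_bp = c(40744000, 41744000))
    # the founder-bearing haplotype (h1 of each carrier) is recovered
    expect_identical(got$carries_mutation, truth_flags,
                     info = paste("seed", seed))
  }
  panel <- build_random_panel(n_hap = 4L, n_markers = 10L, seed = 1L)
  expect_error(assign_carrier_haplotypes(panel, "nope"), "not in panel")
})

test_that("grouping clusters by shared length with deterministic labels", {
  panel <- build_random_panel(n_hap = 4L, n_markers = 20L, miss_rate = 0,
                              seed = 3L)
  focal <- random_focal(panel$map)
  segs <- all_shared_segments(panel, focal)
  # threshold 0: everything shares >= 0 cM -> one cluster
  expect_true(all(group_haplotypes(segs, 0) == 1L))
  # threshold beyond any shared length -> all singletons
  g <- group_haplotypes(segs, max(segs$length_cM) + 1)
  expect_equal(sort(unname(g)), seq_along(g))
})

test_that("two-lineage panels are grouped into the simulated lineages", {
  cfg <- sim_config(n_carriers = 30L, n_controls = 0L, n_lineages = 2L,
                    seed = 2L, genotyping_error_rate = 0, missing_rate = 0)
  sim <- simulate_carrier_panel(cfg)
  segs <- all_shared_segments(sim$panel, cfg$focal)
  grp <- group_haplotypes(segs, min_shared_cM = 0.5)
  expect_equal(length(unique(grp)), 2L)
  truth <- sim$truth$lineage[match(names(grp), sim$truth$carrier_hap_ids)]
  expect_equal(length(unique(grp[truth == 1L])), 1L)
  expect_equal(length(unique(grp[truth == 2L])), 1L)
})
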