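test_that("catalogue partition counts classes, unique and multiallelic positions", {
  # smallest multiallelic case: 3 records at 2 positions
  cat3 <- make_catalogue(n_unique = 2, n_multi = 1, n_large_indel = 0)
  p <- glance(partition_catalogue(cat3))
  expect_equal(p$n_positional, 3)
  expect_equal(p$n_unique_positions, 2)
  expect_equal(p$n_multiallelic_positions, 1)

  # class split conserves the total
  cat <- make_catalogue(n_unique = 40, n_multi = 8, n_large_indel = 12)
  p <- glance(partition_catalogue(cat))
  expect_equal(p$n_large_indel + p$n_positional, p$n_total)
  expect_equal(p$n_total, 60)
  expect_true(p$n_multiallelic_positions <= p$n_unique_positions)
})

test_that("partition is order-invariant and matches a grouping oracle", {
  set.seed(41)
  for (rep in 1:3) {
    n_u <- sample(10:60, 1)
    cat <- make_catalogue(
      n_unique = n_u,
      n_multi = sample.int(n_u, 1),
      n_large_indel = sample(0:20, 1)
    )
    shuffled <- cat[sample.int(nrow(cat)), ]
    p1 <- glance(partition_catalogue(cat))
    p2 <- glance(partition_catalogue(shuffled))
    expect_equal(p1, p2)
    oracle <- oracle_partition(cat)
    expect_equal(p1$n_total, oracle$n_total)
    expect_equal(p1$n_large_indel, oracle$n_large_indel)
    expect_equal(p1$n_unique_positions, oracle$n_unique_positions)
    expect_equal(p1$n_multiallelic_positions, oracle$n_multiallelic_positions)
  }
})

test_that("depth_at returns recorded depth, zero when absent, and matches a lookup oracle", {
  set.seed(42)
  panel <- random_panel(10)
  prof <- random_profile(panel)
  expanded <- oracle_expand_profile(prof)
  chroms <- sample(c("chrA", "chrB"), 30, replace = TRUE)
  poss <- sample.int(480, 30)
  got <- depth_at(prof, chroms, poss)
  for (i in 1:30) {
    expect_equal(got[i], oracle_depth_at(expanded, chroms[i], poss[i]))
  }
})

test_that("depth bins partition the integers with an inclusive adequacy threshold", {
  bins <- detectability_bins(20)
  d <- 0:40
  expect_equal(as.character(bin_depth(d, bins)), oracle_bin(d, 20))
  expect_equal(as.character(bin_depth(20L, bins)), "ADEQUATE")
  expect_equal(as.character(bin_depth(19L, bins)), "MID")
  expect_equal(as.character(bin_depth(10L, bins)), "MID")
  expect_equal(as.character(bin_depth(9L, bins)), "LOW")
  expect_equal(as.character(bin_depth(5L, bins)), "LOW")
  expect_equal(as.character(bin_depth(4L, bins)), "VERY_LOW")
})

# build a panel + profile where chosen positions get chosen mean depths
detect_fixture <- function(depths_by_pos) {
  n <- length(depths_by_pos)
  panel <- as_panel(tibble::tibble(
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 100L,
    end = (seq_len(n) - 1L) * 100L + 50L,
    exon_id = sprintf("G1_exon%03d", seq_len(n)),
    gene = "G1"
  ))
  # each variant sits at 1-based pos start+11 (0-based base start+10)
  runs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      chrom = "chr1",
      start = c(panel$start[i], panel$start[i] + 10L, panel$start[i] + 11L),
      end = c(panel$start[i] + 10L, panel$start[i] + 11L, panel$end[i]),
      depth = c(100L, as.integer(depths_by_pos[i]), 100L)
    )
  }))
  prof <- as_depth_profile(runs, panel, "S1")
  variants <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(n)),
    gene = "G1", variant_class = "positional",
    chrom = "chr1", pos = panel$start + 11L,
    ref = "A", alt = "T", hgvs_c = "c.1A>T", pathogenicity = "pathogenic"
  )
  list(panel = panel, profile = prof, variants = as_variant_catalogue(variants))
}

test_that("summary depths bin as published: depths 12,2,11,1,13 give 3 MID and 2 VERY_LOW", {
  fx <- detect_fixture(c(12, 2, 11, 1, 13))
  cap <- assess_capture(fx$panel, fx$panel[, c("chrom", "start", "end")])
  det <- detectability(fx$variants, fx$profile, fx$panel, cap)
  bc <- det$bin_counts
  expect_equal(bc$n_positions[bc$bin == "MID"], 3)
  expect_equal(bc$n_positions[bc$bin == "VERY_LOW"], 2)
  expect_equal(bc$n_positions[bc$bin == "LOW"], 0)
  expect_equal(bc$n_positions[bc$bin == "ADEQUATE"], 0)
  expect_true(all(det$positions$captured))
  expect_equal(det$records$summary_depth, c(12L, 2L, 11L, 1L, 13L))
})

test_that("a summary depth of exactly the threshold is adequate", {
  fx <- detect_fixture(c(20))
  cap <- assess_capture(fx$panel, fx$panel[, c("chrom", "start", "end")])
  det <- detectability(fx$variants, fx$profile, fx$panel, cap)
  expect_equal(as.character(det$records$bin), "ADEQUATE")
})

test_that("mean summary depth floors; median is available by option", {
  fx <- detect_fixture(c(10))
  # second sample with depth 15 at the variant base
  prof2 <- fx$profile
  prof2$sample_id <- "S2"
  prof2$depth[prof2$depth == 10L] <- 15L
  profs <- dplyr::bind_rows(fx$profile, prof2)
  cap <- assess_capture(fx$panel, fx$panel[, c("chrom", "start", "end")])
  det_mean <- detectability(fx$variants, profs, fx$panel, cap, summary = "mean")
  expect_equal(det_mean$records$summary_depth, 12L) # floor(12.5)
  det_med <- detectability(fx$variants, profs, fx$panel, cap, summary = "median")
  expect_equal(det_med$records$summary_depth, 12L) # floor(median(10,15))
})

test_that("bin tallies match a comparison-loop oracle on random variants", {
  set.seed(43)
  depths <- sample(0:60, 100, replace = TRUE)
  fx <- detect_fixture(depths)
  cap <- assess_capture(fx$panel, fx$panel[, c("chrom", "start", "end")])
  det <- detectability(fx$variants, fx$profile, fx$panel, cap)
  oracle <- table(factor(oracle_bin(depths, 20), levels = bin_levels()))
  for (b in bin_levels()) {
    expect_equal(
      det$bin_counts$n_positions[det$bin_counts$bin == b],
      as.integer(oracle[[b]])
    )
  }
  expect_equal(sum(det$bin_counts$n_positions), 100)
})

test_that("raising the threshold only moves variants out of ADEQUATE, never up", {
  set.seed(44)
  depths <- sample(0:60, 50, replace = TRUE)
  fx <- detect_fixture(depths)
  cap <- assess_capture(fx$panel, fx$panel[, c("chrom", "start", "end")])
  det20 <- detectability(fx$variants, fx$profile, fx$panel, cap,
    bins = detectability_bins(20)
  )
  det30 <- detectability(fx$variants, fx$profile, fx$panel, cap,
    bins = detectability_bins(30)
  )
  expect_lte(
    det30$bin_counts$n_positions[det30$bin_counts$bin == "ADEQUATE"],
    det20$bin_counts$n_positions[det20$bin_counts$bin == "ADEQUATE"]
  )
  expect_true(all(det30$records$bin <= det20$records$bin))
})

test_that("large indels are never binned and off-panel variants are excluded but flagged", {
  fx <- detect_fixture(c(30, 30))
  vars <- dplyr::bind_rows(
    fx$variants,
    tibble::tibble(
      variant_id = c("li1", "off1"), gene = "G1",
      variant_class = c("large_indel_no_coordinate", "positional"),
      chrom = c(NA, "chr9"), pos = c(NA, 50L),
      ref = c(NA, "A"), alt = c(NA, "G"),
      hgvs_c = c("c.?_del", "c.5A>G"), pathogenicity = "VUS"
    )
  )
  cap <- assess_capture(fx$panel, fx$panel[, c("chrom", "start", "end")])
  det <- detectability(vars, fx$profile, fx$panel, cap)
  expect_equal(nrow(det$large_indel), 1)
  expect_equal(det$large_indel$variant_id, "li1")
  expect_false(det$records$in_panel[det$records$variant_id == "off1"])
  expect_equal(sum(det$bin_counts$n_positions), 2) # off-panel excluded
  expect_equal(det$summary$n_positions_outside_panel, 1)
})

test_that("multiallelic records share one position-level row but keep per-record rows", {
  fx <- detect_fixture(c(30))
  extra <- fx$variants
  extra$variant_id <- "v_alt"
  extra$alt <- "G"
  vars <- dplyr::bind_rows(fx$variants, extra)
  cap <- assess_capture(fx$panel, fx$panel[, c("chrom", "start", "end")])
  det <- detectability(vars, fx$profile, fx$panel, cap)
  expect_equal(nrow(det$records), 2)
  expect_equal(nrow(det$positions), 1)
  expect_equal(det$positions$n_records, 2)
  expect_equal(sum(det$bin_counts$n_positions), 1)
})
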