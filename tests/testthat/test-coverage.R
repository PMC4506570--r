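one_exon_panel <- function(len = 10L) {
  as_panel(tibble::tibble(
    chrom = "chr1", start = 0L, end = len,
    exon_id = "G1_exon001", gene = "G1"
  ))
}

profile_from_depths <- function(panel, depths, sample_id = "S1") {
  runs <- tibble::tibble(
    chrom = panel$chrom[1],
    start = seq_along(depths) - 1L,
    end = seq_along(depths),
    depth = as.integer(depths)
  )
  as_depth_profile(runs, panel, sample_id)
}

test_that("category boundaries are exact: threshold inclusive, FULL integer-exact", {
  panel <- one_exon_panel(10L)
  scheme <- coverage_scheme(20)

  # all bases exactly at threshold: depth >= 20 is inclusive, so FULL
  st <- exon_coverage(profile_from_depths(panel, rep(20, 10)), panel, scheme)
  expect_equal(st$covered_fraction, 1)
  expect_equal(as.character(st$category), "FULL")

  # 9 of 10 bases adequate: exactly 0.9, WELL (>= 90% and < 100%)
  st <- exon_coverage(profile_from_depths(panel, c(rep(25, 9), 0)), panel, scheme)
  expect_equal(st$covered_fraction, 0.9)
  expect_equal(as.character(st$category), "WELL")

  # 19 is below an inclusive 20x threshold
  st <- exon_coverage(profile_from_depths(panel, rep(19, 10)), panel, scheme)
  expect_equal(st$covered_fraction, 0)
  expect_equal(as.character(st$category), "NONE")

  # all-zero exon
  st <- exon_coverage(profile_from_depths(panel, rep(0, 10)), panel, scheme)
  expect_equal(as.character(st$category), "NONE")
})

test_that("every covered count maps to exactly one category, at the stated cutoffs", {
  L <- 200L
  cats <- classify_coverage(0:L, L)
  expect_false(any(is.na(cats)))
  f <- (0:L) / L
  expect_equal(as.character(cats[f < 0.40]), rep("NONE", sum(f < 0.40)))
  expect_equal(
    as.character(cats[f >= 0.40 & f < 0.70]),
    rep("LIGHT", sum(f >= 0.40 & f < 0.70))
  )
  expect_equal(
    as.character(cats[f >= 0.70 & f < 0.90]),
    rep("MOSTLY", sum(f >= 0.70 & f < 0.90))
  )
  expect_equal(
    as.character(cats[f >= 0.90 & f < 1]),
    rep("WELL", sum(f >= 0.90 & f < 1))
  )
  expect_equal(as.character(cats[f == 1]), "FULL")
})

test_that("covered fractions equal a per-base counting oracle on random exons", {
  set.seed(31)
  panel <- random_panel(40)
  prof <- random_profile(panel, max_depth = 40)
  scheme <- coverage_scheme(20)
  st <- exon_coverage(prof, panel, scheme)
  expanded <- oracle_expand_profile(prof)
  for (i in seq_len(nrow(panel))) {
    expect_equal(
      st$n_bases_at_threshold[st$exon_id == panel$exon_id[i]],
      oracle_covered_count(expanded, panel[i, ], 20L),
      info = panel$exon_id[i]
    )
  }
})

test_that("raising the depth threshold never raises a fraction or a category", {
  set.seed(32)
  panel <- random_panel(25)
  prof <- random_profile(panel, max_depth = 45)
  st10 <- exon_coverage(prof, panel, coverage_scheme(10))
  st20 <- exon_coverage(prof, panel, coverage_scheme(20))
  st30 <- exon_coverage(prof, panel, coverage_scheme(30))
  expect_true(all(st20$covered_fraction <= st10$covered_fraction))
  expect_true(all(st30$covered_fraction <= st20$covered_fraction))
  expect_true(all(st20$category <= st10$category))
  expect_true(all(st30$category <= st20$category))
})

test_that("per-sample proportions tally categories and always sum to one", {
  # degenerate: every exon FULL
  stats <- tibble::tibble(
    sample_id = "S1", exon_id = sprintf("e%d", 1:4),
    category = factor("FULL", levels = coverage_categories(), ordered = TRUE)
  )
  p <- sample_category_proportions(stats)
  expect_equal(p$proportion[p$category == "FULL"], 1)
  expect_equal(sum(p$proportion), 1)

  # the 81/5/5/3/6 split
  cats <- rep(
    c("FULL", "WELL", "MOSTLY", "LIGHT", "NONE"),
    c(81, 5, 5, 3, 6)
  )
  stats <- tibble::tibble(
    sample_id = "S1", exon_id = sprintf("e%d", seq_along(cats)),
    category = factor(cats, levels = coverage_categories(), ordered = TRUE)
  )
  p <- sample_category_proportions(stats)
  expect_equal(
    p$proportion[order(p$category, decreasing = TRUE)],
    c(0.81, 0.05, 0.05, 0.03, 0.06)
  )

  expect_error(sample_category_proportions(stats[0, ]), class = "panelcov_bad_input")

  # random tallies agree with table()
  set.seed(33)
  cats <- sample(coverage_categories(), 200, replace = TRUE)
  stats <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 100),
    exon_id = rep(sprintf("e%d", 1:100), 2),
    category = factor(cats, levels = coverage_categories(), ordered = TRUE)
  )
  p <- sample_category_proportions(stats)
  for (s in c("A", "B")) {
    tab <- table(cats[stats$sample_id == s])
    for (cat in names(tab)) {
      expect_equal(
        p$n_exons[p$sample_id == s & p$category == cat],
        as.integer(tab[[cat]])
      )
    }
    expect_equal(sum(p$proportion[p$sample_id == s]), 1, tolerance = 1e-12)
  }
})

test_that("averaging proportions is the unweighted mean across samples", {
  one <- tibble::tibble(
    sample_id = "S1",
    category = factor(coverage_categories(),
      levels = coverage_categories(), ordered = TRUE
    ),
    n_exons = c(0L, 0L, 0L, 0L, 10L),
    proportion = c(0, 0, 0, 0, 1)
  )
  avg <- average_proportions(one)
  expect_equal(avg$mean_proportion[avg$category == "FULL"], 1)

  two <- dplyr::bind_rows(
    one,
    dplyr::mutate(one,
      sample_id = "S2",
      proportion = c(0, 0, 0, 1, 0), n_exons = c(0L, 0L, 0L, 10L, 0L)
    )
  )
  avg <- average_proportions(two)
  expect_equal(avg$mean_proportion[avg$category == "FULL"], 0.5)
  expect_equal(avg$mean_proportion[avg$category == "WELL"], 0.5)
  expect_equal(sum(avg$mean_proportion), 1)

  set.seed(34)
  many <- dplyr::bind_rows(lapply(1:12, function(i) {
    pr <- runif(5)
    tibble::tibble(
      sample_id = sprintf("S%02d", i),
      category = factor(coverage_categories(),
        levels = coverage_categories(), ordered = TRUE
      ),
      n_exons = 0L, proportion = pr / sum(pr)
    )
  }))
  avg <- average_proportions(many)
  for (cat in coverage_categories()) {
    manual <- mean(many$proportion[many$category == cat])
    expect_equal(avg$mean_proportion[avg$category == cat], manual)
  }
})

test_that("mean exon fraction averages across samples and flags missing ones", {
  stats <- tibble::tibble(
    sample_id = rep(c("S1", "S2"), each = 2),
    exon_id = rep(c("e1", "e2"), 2),
    gene = "G1",
    covered_fraction = c(0.5, 0, 0.5, 1)
  )
  m <- mean_exon_fraction(stats)
  expect_equal(m$mean_covered_fraction[m$exon_id == "e1"], 0.5)
  expect_equal(m$mean_covered_fraction[m$exon_id == "e2"], 0.5)

  expect_error(
    mean_exon_fraction(stats[-4, ]), "S2",
    class = "panelcov_bad_input"
  )
})

test_that("no-coverage position counts use the best containing exon per sample", {
  panel <- as_panel(tibble::tibble(
    chrom = "chr1", start = c(0L, 5L, 100L), end = c(20L, 25L, 130L),
    exon_id = c("G1_exon001", "G1_exon002", "G1_exon003"), gene = "G1"
  ))
  mk_stats <- function(sample_id, cats) {
    tibble::tibble(
      sample_id = sample_id, exon_id = panel$exon_id, gene = "G1",
      category = factor(cats, levels = coverage_categories(), ordered = TRUE)
    )
  }
  positions <- tibble::tibble(
    chrom = "chr1",
    pos = c(10L, 22L, 105L, 110L, 115L, 400L)
  )
  # S1: overlap position 10 sits in a NONE and a FULL exon -> not counted;
  # exon3 is NONE and holds 3 positions
  stats <- dplyr::bind_rows(
    mk_stats("S1", c("NONE", "FULL", "NONE")),
    mk_stats("S2", c("FULL", "FULL", "FULL"))
  )
  res <- positions_in_none_exons(positions, stats, panel)
  expect_equal(
    res$per_sample$n_positions_none[res$per_sample$sample_id == "S1"], 3
  )
  expect_equal(
    res$per_sample$n_positions_none[res$per_sample$sample_id == "S2"], 0
  )
  expect_equal(res$summary$n_positions_considered, 5) # 400 is outside
  expect_equal(res$summary$min, 0)
  expect_equal(res$summary$max, 3)
  expect_equal(res$summary$median, 1.5) # even cohort: mean of central pair
})

test_that("no-coverage position counts match an exhaustive double loop", {
  set.seed(35)
  panel <- random_panel(20)
  profiles <- dplyr::bind_rows(
    random_profile(panel, "S1", max_depth = 30),
    random_profile(panel, "S2", max_depth = 30)
  )
  stats <- exon_coverage(profiles, panel, coverage_scheme(20))
  positions <- dplyr::distinct(tibble::tibble(
    chrom = sample(c("chrA", "chrB"), 50, replace = TRUE),
    pos = sample.int(450, 50, replace = TRUE)
  ))
  res <- positions_in_none_exons(positions, stats, panel)
  for (s in c("S1", "S2")) {
    st <- stats[stats$sample_id == s, ]
    brute <- 0L
    for (i in seq_len(nrow(positions))) {
      ids <- oracle_position_exons(positions$chrom[i], positions$pos[i], panel)
      if (length(ids) == 0) next
      cats <- st$category[match(ids, st$exon_id)]
      if (all(as.character(cats) == "NONE")) brute <- brute + 1L
    }
    expect_equal(
      res$per_sample$n_positions_none[res$per_sample$sample_id == s],
      brute
    )
  }
})

test_that("coverage_summary restricts the denominator to captured exons by default", {
  panel <- as_panel(tibble::tibble(
    chrom = "chr1", start = c(0L, 100L), end = c(10L, 110L),
    exon_id = c("G1_exon001", "G1_exon002"), gene = "G1"
  ))
  design <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  cap <- assess_capture(panel, design)
  prof <- as_depth_profile(
    tibble::tibble(chrom = "chr1", start = 0L, end = 10L, depth = 30L),
    panel, "S1"
  )
  res <- coverage_summary(prof, panel, capture = cap)
  # only the captured exon counts: proportions are over 1 exon
  expect_equal(sum(res$proportions$n_exons), 1)
  expect_equal(
    res$mean_proportions$mean_proportion[res$mean_proportions$category == "FULL"], 1
  )
  res_all <- coverage_summary(prof, panel, capture = cap, denominator = "all")
  expect_equal(
    res_all$mean_proportions$mean_proportion[res_all$mean_proportions$category == "FULL"], 0.5
  )
  expect_error(coverage_summary(prof, panel), class = "panelcov_bad_input")
})
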