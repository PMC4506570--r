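#' Coverage category scheme
#'
#' Defines adequate depth (`depth >= depth_threshold`, inclusive) and the
#' five-tier classification of an exon's covered fraction `f` (the fraction
#' of its bases at adequate depth):
#' * `FULL` — `f == 1` (an exact integer condition: every base adequate);
#' * `WELL` — `0.90 <= f < 1`;
#' * `MOSTLY` — `0.70 <= f < 0.90`;
#' * `LIGHT` — `0.40 <= f < 0.70`;
#' * `NONE` — `f < 0.40`.
#'
#' The three interior boundaries can be moved via `breaks`; the partition of
#' `[0, 1]` is always exact (every fraction maps to exactly one tier).
#'
#' @param depth_threshold read depth defining an adequately sequenced base
#'   (default 20, i.e. "20x").
#' @param breaks ascending boundaries between NONE/LIGHT, LIGHT/MOSTLY and
#'   MOSTLY/WELL on the covered fraction.
#' @return an object of class `panelcov_scheme`.
#' @export
coverage_scheme <- function(depth_threshold = 20L, breaks = c(0.40, 0.70, 0.90)) {
  stopifnot(
    depth_threshold >= 1, length(breaks) == 3,
    !is.unsorted(breaks, strictly = TRUE), breaks[1] > 0, breaks[3] < 1
  )
  structure(
    list(depth_threshold = as.integer(depth_threshold), breaks = breaks),
    class = "panelcov_scheme"
  )
}

#' Coverage category levels, lowest to highest tier
#' @return character vector `NONE < LIGHT < MOSTLY < WELL < FULL`.
#' @export
coverage_categories <- function() c("NONE", "LIGHT", "MOSTLY", "WELL", "FULL")

#' Classify covered base counts into coverage categories
#'
#' `FULL` is decided by the exact integer comparison
#' `n_at_threshold == n_bases`, never by a floating-point `f >= 1` test.
#'
#' @param n_at_threshold bases at adequate depth (vector).
#' @param n_bases exon sizes (vector).
#' @param scheme a [coverage_scheme()].
#' @return ordered factor of categories.
#' @export
classify_coverage <- function(n_at_threshold, n_bases, scheme = coverage_scheme()) {
  stopifnot(all(n_bases >= 1), all(n_at_threshold >= 0), all(n_at_threshold <= n_bases))
  f <- n_at_threshold / n_bases
  b <- scheme$breaks
  out <- ifelse(n_at_threshold == n_bases, "FULL",
    ifelse(f >= b[3], "WELL",
      ifelse(f >= b[2], "MOSTLY",
        ifelse(f >= b[1], "LIGHT", "NONE")
      )
    )
  )
  factor(out, levels = coverage_categories(), ordered = TRUE)
}

#' Per-exon covered fraction and category for each sample
#'
#' For every (sample, exon) pair, counts the exon bases whose depth reaches
#' the scheme's threshold, computes the covered fraction, and classifies it.
#' Profile bases absent from a run are depth 0, so an exon with no reads has
#' fraction 0 and category `NONE`.
#'
#' @param profiles depth-profile tibble, one or more samples (row-bound).
#' @param panel panel tibble of exons.
#' @param scheme a [coverage_scheme()].
#' @return tibble with one row per sample x exon: `sample_id`, `exon_id`,
#'   `gene`, `n_bases`, `n_bases_at_threshold`, `covered_fraction`,
#'   `category`.
#' @export
exon_coverage <- function(profiles, panel, scheme = coverage_scheme()) {
  panel <- as_panel(panel)
  profiles <- as_tibble(profiles)
  check_columns(profiles, c("sample_id", "chrom", "start", "end", "depth"), "profiles")
  exon_gr <- gr_from_intervals(panel)
  d <- scheme$depth_threshold

  one_sample <- function(runs) {
    n_at <- integer(nrow(panel))
    hi <- runs[runs$depth >= d, , drop = FALSE]
    if (nrow(hi) > 0) {
      hi_gr <- gr_from_intervals(hi)
      hits <- GenomicRanges::findOverlaps(exon_gr, hi_gr)
      if (length(hits) > 0) {
        w <- IRanges::width(IRanges::pintersect(
          exon_gr[S4Vectors::queryHits(hits)],
          hi_gr[S4Vectors::subjectHits(hits)]
        ))
        agg <- tapply(w, S4Vectors::queryHits(hits), sum)
        n_at[as.integer(names(agg))] <- as.integer(agg)
      }
    }
    tibble(
      exon_id = panel$exon_id,
      gene = panel$gene,
      n_bases = panel$end - panel$start,
      n_bases_at_threshold = n_at
    )
  }

  profiles |>
    tidyr::nest(runs = -"sample_id") |>
    mutate(stats = purrr::map(.data$runs, one_sample)) |>
    select("sample_id", "stats") |>
    tidyr::unnest("stats") |>
    mutate(
      covered_fraction = .data$n_bases_at_threshold / .data$n_bases,
      category = classify_coverage(.data$n_bases_at_threshold, .data$n_bases, scheme)
    )
}

#' Per-sample coverage-category proportions
#'
#' The share of exons in each of the five tiers, per sample. The five
#' proportions of a sample sum to 1 exactly.
#'
#' @param stats exon-coverage tibble from [exon_coverage()], typically
#'   restricted to captured exons beforehand.
#' @return long tibble: `sample_id`, `category`, `n_exons`, `proportion`.
#' @export
sample_category_proportions <- function(stats) {
  stats <- as_tibble(stats)
  if (nrow(stats) == 0) {
    pc_abort("no exon coverage statistics supplied", class = "panelcov_bad_input")
  }
  stats |>
    group_by(.data$sample_id) |>
    count(category = factor(.data$category,
      levels = coverage_categories(), ordered = TRUE
    ), .drop = FALSE, name = "n_exons") |>
    mutate(proportion = .data$n_exons / sum(.data$n_exons)) |>
    ungroup()
}

#' Cross-sample mean of category proportions
#'
#' Unweighted arithmetic mean of each tier's proportion across samples
#' (every sample counts equally, whatever its exon denominator).
#'
#' @param proportions long tibble from [sample_category_proportions()].
#' @return tibble: `category`, `mean_proportion`, `pct` (mean as a
#'   percentage, half-up to 2 decimals).
#' @export
average_proportions <- function(proportions) {
  stopifnot(nrow(proportions) > 0)
  proportions |>
    group_by(.data$category) |>
    summarise(mean_proportion = mean(.data$proportion), .groups = "drop") |>
    mutate(pct = round_half_up(100 * .data$mean_proportion, 2)) |>
    arrange(dplyr::desc(.data$category))
}

#' Per-exon mean covered fraction across samples
#'
#' @param stats exon-coverage tibble from [exon_coverage()]. Every exon must
#'   appear in every sample; a missing (sample, exon) pair aborts naming the
#'   sample.
#' @return tibble: `exon_id`, `gene`, `mean_covered_fraction`.
#' @export
mean_exon_fraction <- function(stats) {
  stats <- as_tibble(stats)
  counts <- count(stats, .data$sample_id, name = "n_exons")
  n_exons <- length(unique(stats$exon_id))
  short <- counts$sample_id[counts$n_exons < n_exons]
  if (length(short) > 0) {
    pc_abort(sprintf(
      "sample '%s' is missing exon coverage records", short[1]
    ), class = "panelcov_bad_input")
  }
  stats |>
    group_by(.data$exon_id, .data$gene) |>
    summarise(mean_covered_fraction = mean(.data$covered_fraction), .groups = "drop") |>
    arrange(.data$exon_id)
}

#' Catalogued positions falling in "no coverage" exons, per sample
#'
#' For each sample, counts the unique catalogued positions whose best
#' containing exon (highest tier among the exons in `stats` that contain
#' the position, in that sample) is `NONE` — the positions at risk of being
#' missed for depth reasons. A position inside both a `NONE` and a
#' higher-tier exon is adequately sequenced in the better context and is
#' not counted. Positions in no `stats` exon are excluded from
#' consideration.
#'
#' @param positions data frame with columns `chrom`, `pos` (1-based);
#'   deduplicated internally.
#' @param stats exon-coverage tibble from [exon_coverage()] (typically
#'   captured exons only).
#' @param panel panel tibble of exons.
#' @return list with
#'   * `per_sample` — tibble `sample_id`, `n_positions_none`;
#'   * `summary` — one-row tibble with `min`, `max`, `median`, `mean`
#'     counts, the number of positions considered, and
#'     `pct_positions_none` = 100 * mean / considered (half-up, 1 decimal).
#' @export
positions_in_none_exons <- function(positions, stats, panel) {
  positions <- distinct(as_tibble(positions)[, c("chrom", "pos")])
  stats <- as_tibble(stats)
  hits <- join_positions_exons(positions, panel)
  hits <- hits[hits$exon_id %in% unique(stats$exon_id), , drop = FALSE]
  n_considered <- nrow(distinct(hits[, c("chrom", "pos")]))

  per_sample <- stats |>
    select("sample_id", "exon_id", "category") |>
    inner_join(hits, by = "exon_id", relationship = "many-to-many") |>
    group_by(.data$sample_id, .data$chrom, .data$pos) |>
    summarise(best = max(.data$category), .groups = "drop") |>
    group_by(.data$sample_id) |>
    summarise(n_positions_none = sum(.data$best == "NONE"), .groups = "drop")

  # samples with no qualifying positions still get a zero row
  all_samples <- tibble(sample_id = sort(unique(stats$sample_id)))
  per_sample <- all_samples |>
    left_join(per_sample, by = "sample_id") |>
    mutate(n_positions_none = dplyr::coalesce(.data$n_positions_none, 0L))

  x <- per_sample$n_positions_none
  summary <- tibble(
    n_samples = length(x),
    min = min(x), max = max(x),
    median = median(x), mean = mean(x),
    n_positions_considered = n_considered,
    pct_positions_none = pct_of(mean(x), n_considered)
  )
  list(per_sample = per_sample, summary = summary)
}

#' Full coverage summary for a cohort
#'
#' Convenience wrapper chaining [exon_coverage()] (optionally restricted to
#' captured exons), [sample_category_proportions()],
#' [average_proportions()], [mean_exon_fraction()], and — when catalogued
#' positions are supplied — [positions_in_none_exons()].
#'
#' @param profiles multi-sample depth-profile tibble.
#' @param panel panel tibble of exons.
#' @param scheme a [coverage_scheme()].
#' @param capture optional `panelcov_capture`; with
#'   `denominator = "captured"` (the default) category proportions and the
#'   no-coverage position counts are computed over captured exons only.
#' @param positions optional catalogued positions (`chrom`, `pos`).
#' @param denominator `"captured"` or `"all"`.
#' @return an object of class `panelcov_coverage`: list with `stats`,
#'   `proportions`, `mean_proportions`, `exon_means`, `none_positions`
#'   (or NULL), `scheme`, `denominator`.
#' @export
coverage_summary <- function(profiles, panel, scheme = coverage_scheme(),
                             capture = NULL, positions = NULL,
                             denominator = c("captured", "all")) {
  denominator <- match.arg(denominator)
  if (denominator == "captured" && is.null(capture)) {
    pc_abort("denominator = 'captured' requires a capture assessment",
      class = "panelcov_bad_input"
    )
  }
  stats_all <- exon_coverage(profiles, panel, scheme)
  stats <- if (denominator == "captured") {
    filter(stats_all, .data$exon_id %in% captured_exons(capture))
  } else {
    stats_all
  }
  proportions <- sample_category_proportions(stats)
  none_positions <- if (!is.null(positions)) {
    positions_in_none_exons(positions, stats, panel)
  }
  structure(
    list(
      stats = stats_all,
      proportions = proportions,
      mean_proportions = average_proportions(proportions),
      exon_means = mean_exon_fraction(stats_all),
      none_positions = none_positions,
      scheme = scheme,
      denominator = denominator
    ),
    class = "panelcov_coverage"
  )
}

#' @export
print.panelcov_coverage <- function(x, ...) {
  mp <- x$mean_proportions
  cat(sprintf(
    "<panelcov_coverage> %d samples, %d exons (%s denominator), depth threshold %dx\n",
    length(unique(x$proportions$sample_id)),
    length(unique(x$stats$exon_id)),
    x$denominator, x$scheme$depth_threshold
  ))
  cat("mean category proportions (%):\n")
  cat(paste(sprintf("  %-6s %6.2f", mp$category, mp$pct), collapse = "\n"), "\n")
  invisible(x)
}
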