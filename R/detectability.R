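#' Partition a variant catalogue by class and position multiplicity
#'
#' Splits records into coordinate-free large indels (which exome sequencing
#' cannot localise and which are excluded from position-level analysis) and
#' positional records; among the latter, counts distinct (chrom, pos)
#' positions and how many carry two or more distinct records (multiallelic
#' positions). Percentages follow the catalogue-report convention: class
#' shares over all records, unique/multiallelic shares over positional
#' records, half-up to 1 decimal.
#'
#' @param variants validated catalogue tibble (see
#'   [as_variant_catalogue()]).
#' @return an object of class `panelcov_partition`: list with
#'   * `summary` — one-row tibble of the counts and percentages;
#'   * `positions` — per-unique-position tibble with `n_records`.
#' @export
partition_catalogue <- function(variants) {
  variants <- as_variant_catalogue(variants)
  n_total <- nrow(variants)
  positional <- filter(variants, .data$variant_class == "positional")
  n_li <- n_total - nrow(positional)

  positions <- positional |>
    count(.data$chrom, .data$pos, name = "n_records") |>
    arrange(.data$chrom, .data$pos)
  n_unique <- nrow(positions)
  n_multi <- sum(positions$n_records >= 2)

  summary <- tibble(
    n_total = n_total,
    n_large_indel = n_li,
    n_positional = nrow(positional),
    n_unique_positions = n_unique,
    n_multiallelic_positions = n_multi,
    pct_large_indel = pct_of(n_li, n_total),
    pct_positional = pct_of(nrow(positional), n_total),
    pct_unique_positions = pct_of(n_unique, nrow(positional)),
    pct_multiallelic_positions = pct_of(n_multi, nrow(positional))
  )
  structure(
    list(summary = summary, positions = positions),
    class = "panelcov_partition"
  )
}

#' @export
print.panelcov_partition <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<panelcov_partition> %d records: %d large indels without coordinates (%.1f%%), %d positional (%.1f%%)\n",
    s$n_total, s$n_large_indel, s$pct_large_indel, s$n_positional, s$pct_positional
  ))
  cat(sprintf(
    "  %d unique positions (%.1f%%), %d multiallelic (%.1f%%)\n",
    s$n_unique_positions, s$pct_unique_positions,
    s$n_multiallelic_positions, s$pct_multiallelic_positions
  ))
  invisible(x)
}

#' Depth at 1-based positions
#'
#' Looks up the read depth of a depth profile at given positions. Positions
#' outside the profile's footprint return 0.
#'
#' @param profile single-sample depth-profile tibble.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 1-based positions.
#' @return integer vector of depths.
#' @export
depth_at <- function(profile, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  stopifnot(all(pos >= 1))
  pos_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
  run_gr <- gr_from_intervals(profile)
  hits <- GenomicRanges::findOverlaps(pos_gr, run_gr)
  out <- integer(n)
  out[S4Vectors::queryHits(hits)] <- as.integer(profile$depth[S4Vectors::subjectHits(hits)])
  out
}

#' Detectability depth bins
#'
#' Partition of the non-negative integers by sequencing depth `d`:
#' `ADEQUATE` (`d >= depth_threshold`), `MID` (`10 <= d < depth_threshold`),
#' `LOW` (`5 <= d < 10`), `VERY_LOW` (`d < 5`). A variant at an `ADEQUATE`
#' position is expected to be picked up; lower bins carry increasing risk of
#' a missed call.
#'
#' @param depth_threshold adequate-depth cutoff (default 20).
#' @return an object of class `panelcov_bins`.
#' @export
detectability_bins <- function(depth_threshold = 20L) {
  stopifnot(depth_threshold > 10)
  structure(
    list(depth_threshold = as.integer(depth_threshold)),
    class = "panelcov_bins"
  )
}

#' Bin level names, lowest depth first
#' @return character vector `VERY_LOW < LOW < MID < ADEQUATE`.
#' @export
bin_levels <- function() c("VERY_LOW", "LOW", "MID", "ADEQUATE")

#' Assign depths to detectability bins
#'
#' @param depth integer vector of depths.
#' @param bins a [detectability_bins()].
#' @return ordered factor over [bin_levels()].
#' @export
bin_depth <- function(depth, bins = detectability_bins()) {
  stopifnot(all(depth >= 0))
  d <- bins$depth_threshold
  out <- ifelse(depth >= d, "ADEQUATE",
    ifelse(depth >= 10, "MID", ifelse(depth >= 5, "LOW", "VERY_LOW"))
  )
  factor(out, levels = bin_levels(), ordered = TRUE)
}

#' Would the catalogued variants be picked up? Depth-bin each position
#'
#' For every positional variant: looks up its per-sample depth, summarises
#' across samples (`mean` by default, `median` by option; either way rounded
#' down to an integer), bins the summary depth, and flags whether the
#' variant's containing exon(s) are captured (captured-dominates, as in
#' [partition_positions_by_capture()]). Variants falling in no panel exon
#' are flagged (`in_panel = FALSE`) and excluded from the bin aggregates.
#' Coordinate-free large indels are never binned; they are returned in a
#' separate `large_indel` table as not assessable by depth.
#'
#' Records sharing a position share the position's depth and bin (a
#' well-sequenced position is covered regardless of the base change);
#' position-level rows are returned in `positions` alongside the per-record
#' rows.
#'
#' @param variants validated catalogue tibble.
#' @param profiles multi-sample depth-profile tibble.
#' @param panel panel tibble of exons.
#' @param capture a `panelcov_capture` for the same panel.
#' @param bins a [detectability_bins()].
#' @param summary `"mean"` or `"median"` across samples.
#' @return an object of class `panelcov_detectability`: list with
#'   * `records` — per positional record: `variant_id`, `gene`, `chrom`,
#'     `pos`, `in_panel`, `captured`, `summary_depth`, `bin`;
#'   * `positions` — the same at (chrom, pos) level with `n_records`;
#'   * `bin_counts` — per-bin position... record counts (see columns);
#'   * `large_indel` — the coordinate-free records, not assessable;
#'   * `summary` — one-row aggregate tibble.
#' @export
detectability <- function(variants, profiles, panel, capture,
                          bins = detectability_bins(),
                          summary = c("mean", "median")) {
  summary <- match.arg(summary)
  variants <- as_variant_catalogue(variants)
  profiles <- as_tibble(profiles)
  sample_ids <- unique(profiles$sample_id)
  if (length(sample_ids) < 1) {
    pc_abort("at least one depth profile is required", class = "panelcov_bad_input")
  }
  large_indel <- filter(variants, .data$variant_class == "large_indel_no_coordinate")
  positional <- filter(variants, .data$variant_class == "positional")

  upos <- distinct(positional[, c("chrom", "pos")])
  # per-sample depth at each unique position
  depths <- profiles |>
    tidyr::nest(runs = -"sample_id") |>
    mutate(d = purrr::map(.data$runs, function(r) {
      tibble(upos, depth = as.integer(depth_at(r, upos$chrom, upos$pos)))
    })) |>
    select("sample_id", "d") |>
    tidyr::unnest("d")
  stat_fun <- if (summary == "mean") mean else median
  pos_depth <- depths |>
    group_by(.data$chrom, .data$pos) |>
    summarise(summary_depth = as.integer(floor(stat_fun(.data$depth))), .groups = "drop")

  # capture status per position (captured-dominates across containing exons)
  cap_ids <- captured_exons(capture)
  hits <- join_positions_exons(upos, panel)
  pos_flags <- hits |>
    group_by(.data$chrom, .data$pos) |>
    summarise(captured = any(.data$exon_id %in% cap_ids), .groups = "drop")

  positions <- upos |>
    left_join(count(positional, .data$chrom, .data$pos, name = "n_records"),
      by = c("chrom", "pos")
    ) |>
    left_join(pos_flags, by = c("chrom", "pos")) |>
    mutate(in_panel = !is.na(.data$captured)) |>
    mutate(captured = dplyr::coalesce(.data$captured, FALSE)) |>
    left_join(pos_depth, by = c("chrom", "pos")) |>
    mutate(bin = bin_depth(.data$summary_depth, bins)) |>
    arrange(.data$chrom, .data$pos)

  records <- positional |>
    select("variant_id", "gene", "chrom", "pos", "pathogenicity") |>
    left_join(
      select(positions, "chrom", "pos", "in_panel", "captured", "summary_depth", "bin"),
      by = c("chrom", "pos")
    )

  binned <- filter(positions, .data$in_panel)
  bin_counts <- binned |>
    count(bin = factor(.data$bin, levels = bin_levels(), ordered = TRUE),
      .drop = FALSE, name = "n_positions"
    ) |>
    arrange(dplyr::desc(.data$bin))

  summary_tbl <- tibble(
    n_records = nrow(variants),
    n_large_indel = nrow(large_indel),
    n_positional = nrow(positional),
    n_positions = nrow(positions),
    n_positions_in_panel = nrow(binned),
    n_positions_outside_panel = nrow(positions) - nrow(binned),
    n_captured = sum(binned$captured),
    n_adequate = sum(binned$bin == "ADEQUATE"),
    n_below_threshold = sum(binned$bin != "ADEQUATE"),
    pct_adequate = pct_of(sum(binned$bin == "ADEQUATE"), nrow(binned)),
    summary_stat = summary,
    depth_threshold = bins$depth_threshold,
    n_samples = length(sample_ids)
  )
  structure(
    list(
      records = records, positions = positions, bin_counts = bin_counts,
      large_indel = large_indel, summary = summary_tbl
    ),
    class = "panelcov_detectability"
  )
}

#' @export
print.panelcov_detectability <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<panelcov_detectability> %d positions in panel exons (%s depth over %d samples, threshold %dx)\n",
    s$n_positions_in_panel, s$summary_stat, s$n_samples, s$depth_threshold
  ))
  bc <- x$bin_counts
  cat(paste(sprintf("  %-9s %d", bc$bin, bc$n_positions), collapse = "\n"), "\n")
  if (s$n_large_indel > 0) {
    cat(sprintf(
      "  (+ %d coordinate-free large indels, not assessable by depth)\n",
      s$n_large_indel
    ))
  }
  invisible(x)
}
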