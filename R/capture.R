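#' Assess which panel exons the capture design targets
#'
#' An exon counts as captured when its total overlap with the (normalized)
#' design targets reaches `min_overlap` bases. The default of 1 base is the
#' least-assuming operationalisation of "targeted by the kit"; raise it to
#' demand more of the design. Percentages are reported half-up to 1 decimal
#' alongside the exact counts.
#'
#' @param panel panel tibble of exons (see [as_panel()]).
#' @param design normalized capture-design tibble (`chrom`, `start`, `end`),
#'   e.g. from [read_design_bed()] or [normalize_intervals()]. An empty
#'   design is valid and captures nothing.
#' @param min_overlap minimum overlapping bases for an exon to count as
#'   captured (integer >= 1).
#' @return an object of class `panelcov_capture`: a list with
#'   * `exons` — per-exon tibble with `overlap_bases` and `captured`;
#'   * `summary` — one-row tibble of counts and percentages.
#'   Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
#' @examples
#' panel <- as_panel(tibble::tibble(
#'   chrom = "chrS1", start = c(0L, 100L), end = c(50L, 180L),
#'   exon_id = c("G1_exon1", "G1_exon2"), gene = "G1"
#' ))
#' design <- tibble::tibble(chrom = "chrS1", start = 0L, end = 60L)
#' glance(assess_capture(panel, design))
assess_capture <- function(panel, design, min_overlap = 1L) {
  panel <- as_panel(panel)
  if (nrow(panel) == 0) {
    pc_abort("cannot assess capture of an empty panel", class = "panelcov_bad_input")
  }
  stopifnot(min_overlap >= 1)
  design <- as_tibble(design)
  if (nrow(design) > 0) validate_intervals(design, "capture design")

  ov <- integer(nrow(panel))
  if (nrow(design) > 0) {
    exon_gr <- gr_from_intervals(panel)
    design_gr <- gr_from_intervals(design)
    hits <- GenomicRanges::findOverlaps(exon_gr, design_gr)
    if (length(hits) > 0) {
      w <- IRanges::width(IRanges::pintersect(
        exon_gr[S4Vectors::queryHits(hits)],
        design_gr[S4Vectors::subjectHits(hits)]
      ))
      # design is merged, but sum defensively in case it is not
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  exons <- mutate(panel,
    overlap_bases = ov,
    captured = ov >= min_overlap
  )
  n_total <- nrow(exons)
  n_cap <- sum(exons$captured)
  summary <- tibble(
    n_exons_total = n_total,
    n_captured = n_cap,
    n_not_captured = n_total - n_cap,
    pct_captured = pct_of(n_cap, n_total),
    pct_not_captured = pct_of(n_total - n_cap, n_total),
    min_overlap = as.integer(min_overlap)
  )
  structure(
    list(exons = exons, summary = summary),
    class = "panelcov_capture"
  )
}

#' Captured exon ids of a capture assessment
#'
#' @param capture a `panelcov_capture` object.
#' @return character vector of exon ids flagged captured.
#' @export
captured_exons <- function(capture) {
  capture$exons$exon_id[capture$exons$captured]
}

#' Partition catalogued positions by the capture status of their exons
#'
#' Deduplicates positions by (chrom, pos) and assigns each in-exon position
#' to the captured side if at least one containing exon is captured
#' (captured-dominates: a base is detectable if any targeted context covers
#' it), and to the non-captured side only if every containing exon is
#' non-captured. Positions in no panel exon are counted separately and enter
#' neither side.
#'
#' @param positions data frame with columns `chrom`, `pos` (1-based).
#' @param panel panel tibble of exons.
#' @param capture a `panelcov_capture` object for the same panel.
#' @return an object of class `panelcov_positions`: list with
#'   * `positions` — per-unique-position tibble with `in_exon` and
#'     `captured`;
#'   * `summary` — one-row tibble of counts and percentages (denominator:
#'     unique positions falling in any exon).
#' @export
partition_positions_by_capture <- function(positions, panel, capture) {
  positions <- distinct(as_tibble(positions)[, c("chrom", "pos")])
  hits <- join_positions_exons(positions, panel)
  cap_ids <- captured_exons(capture)
  status <- hits |>
    group_by(.data$chrom, .data$pos) |>
    summarise(captured = any(.data$exon_id %in% cap_ids), .groups = "drop")
  out <- positions |>
    left_join(status, by = c("chrom", "pos")) |>
    mutate(in_exon = !is.na(.data$captured))

  n_in_exon <- sum(out$in_exon)
  n_cap <- sum(out$captured, na.rm = TRUE)
  n_not <- n_in_exon - n_cap
  summary <- tibble(
    n_positions_total = nrow(out),
    n_positions_in_exon = n_in_exon,
    n_positions_outside_exons = nrow(out) - n_in_exon,
    n_positions_in_captured = n_cap,
    n_positions_in_not_captured = n_not,
    pct_in_captured = pct_of(n_cap, n_in_exon),
    pct_in_not_captured = pct_of(n_not, n_in_exon)
  )
  structure(
    list(positions = out, summary = summary),
    class = "panelcov_positions"
  )
}

#' @importFrom dplyr distinct
#' @export
print.panelcov_capture <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<panelcov_capture> %d exons: %d captured (%.1f%%), %d not captured (%.1f%%) at min_overlap=%d\n",
    s$n_exons_total, s$n_captured, s$pct_captured,
    s$n_not_captured, s$pct_not_captured, s$min_overlap
  ))
  invisible(x)
}

#' @export
print.panelcov_positions <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<panelcov_positions> %d unique positions: %d in captured exons (%.1f%%), %d only in non-captured (%.1f%%), %d outside exons\n",
    s$n_positions_in_exon, s$n_positions_in_captured, s$pct_in_captured,
    s$n_positions_in_not_captured, s$pct_in_not_captured,
    s$n_positions_outside_exons
  ))
  invisible(x)
}
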