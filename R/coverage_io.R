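#' Depth profiles, variant catalogues, manifests, and report writers
#'
#' A depth profile is the per-base read depth of one sample over the panel
#' exon footprint, carried run-length encoded: a tibble with columns
#' `sample_id`, `chrom`, `start`, `end`, `depth` whose runs are disjoint and
#' cover the footprint exactly. Bases absent from the source table have
#' depth 0. Multi-sample profiles are simply row-bound single-sample ones.
#'
#' @name coverage-io
NULL

#' Panel exon footprint
#'
#' The union of the panel's exon intervals, merged and sorted.
#'
#' @param panel panel tibble of exons.
#' @return tibble of disjoint intervals (`chrom`, `start`, `end`).
#' @export
panel_footprint <- function(panel) {
  normalize_intervals(panel[, c("chrom", "start", "end")])
}

#' Build a depth profile from depth runs
#'
#' Clips the runs to the panel footprint, fills uncovered footprint bases
#' with depth 0, and merges adjacent runs of equal depth. Bases of the input
#' lying outside the footprint are dropped; their count is kept in the
#' `n_outside_bases` attribute.
#'
#' @param runs data frame with columns `chrom`, `start`, `end`, `depth`
#'   (0-based half-open, non-negative integer depth). Overlapping runs are
#'   an error.
#' @param panel panel tibble of exons.
#' @param sample_id sample identifier attached to every row.
#' @return a depth-profile tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `depth`).
#' @export
as_depth_profile <- function(runs, panel, sample_id) {
  runs <- as_tibble(runs)
  check_columns(runs, c("chrom", "start", "end", "depth"), "depth runs")
  if (nrow(runs) > 0) {
    validate_intervals(runs, "depth runs")
    if (any(is.na(runs$depth) | runs$depth < 0)) {
      pc_abort("depths must be non-negative", class = "panelcov_bad_input")
    }
  }
  fp <- panel_footprint(panel)
  fp_gr <- gr_from_intervals(fp)

  if (nrow(runs) > 0) {
    run_gr <- gr_from_intervals(runs)
    cov <- sum(IRanges::width(GenomicRanges::reduce(run_gr)))
    if (cov < sum(runs$end - runs$start)) {
      pc_abort("depth runs overlap each other", class = "panelcov_bad_input")
    }
    hits <- GenomicRanges::findOverlaps(run_gr, fp_gr)
    inter <- IRanges::pintersect(
      run_gr[S4Vectors::queryHits(hits)],
      fp_gr[S4Vectors::subjectHits(hits)]
    )
    kept <- tibble(
      chrom = as.character(GenomicRanges::seqnames(inter)),
      start = GenomicRanges::start(inter) - 1L,
      end = GenomicRanges::end(inter),
      depth = as.integer(runs$depth[S4Vectors::queryHits(hits)])
    )
    n_outside <- sum(runs$end - runs$start) - sum(kept$end - kept$start)
  } else {
    kept <- tibble(
      chrom = character(), start = integer(), end = integer(),
      depth = integer()
    )
    n_outside <- 0L
  }

  # fill footprint gaps with zero-depth runs
  gap_gr <- GenomicRanges::setdiff(fp_gr, gr_from_intervals(kept))
  gaps <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gap_gr)),
    start = GenomicRanges::start(gap_gr) - 1L,
    end = GenomicRanges::end(gap_gr),
    depth = 0L
  )
  out <- arrange(bind_rows(kept, gaps), .data$chrom, .data$start)

  # merge adjacent runs with equal depth
  out <- out |>
    group_by(.data$chrom) |>
    mutate(new_run = row_number() == 1 |
      .data$start != lag(.data$end) | .data$depth != lag(.data$depth)) |>
    mutate(run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      depth = first(.data$depth), .groups = "drop"
    ) |>
    select("chrom", "start", "end", "depth") |>
    arrange(.data$chrom, .data$start)

  out <- tibble(sample_id = sample_id, out)
  attr(out, "n_outside_bases") <- as.integer(n_outside)
  out
}

#' Read a per-sample depth table
#'
#' Accepts either of two dialects:
#' * per-base BED: 4 tab-separated columns `chrom, start, end, depth`
#'   (0-based half-open, run-length encoded);
#' * per-locus TSV in the GATK DepthOfCoverage style: `chrom:pos<TAB>depth`
#'   with a 1-based locus key and an optional header line.
#'
#' The dialect is detected from the first data line (a `:` in the first
#' field means per-locus). Footprint bases not mentioned in the file get
#' depth 0; loci outside the panel footprint are dropped and counted in the
#' `n_outside_bases` attribute. A malformed row aborts with its line number.
#'
#' @param path file path.
#' @param panel panel tibble of exons.
#' @param sample_id sample identifier (default: file name without extension).
#' @return a depth-profile tibble (see [as_depth_profile()]).
#' @export
read_depth_table <- function(path, panel, sample_id = NULL) {
  if (!file.exists(path)) {
    pc_abort(sprintf("depth table not found: '%s'", path),
      class = "panelcov_missing_file"
    )
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(as_depth_profile(
      tibble(chrom = character(), start = integer(), end = integer(), depth = integer()),
      panel, sample_id
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  per_locus <- grepl(":", fields[[1]][1], fixed = TRUE) ||
    (length(fields) > 1 && grepl(":", fields[[2]][1], fixed = TRUE))
  if (per_locus) {
    # tolerate a single header line (e.g. "Locus\tTotal_Depth")
    if (!grepl(":", fields[[1]][1], fixed = TRUE)) {
      fields <- fields[-1]
      lineno <- lineno[-1]
    }
    runs <- parse_locus_rows(fields, lineno, path)
  } else {
    runs <- parse_depth_bed_rows(fields, lineno, path)
  }
  as_depth_profile(runs, panel, sample_id)
}

parse_locus_rows <- function(fields, lineno, path) {
  nf <- lengths(fields)
  bad <- which(nf < 2)
  col1 <- vapply(fields, `[`, character(1), 1)
  col2 <- vapply(fields, function(f) if (length(f) >= 2) f[2] else NA_character_, character(1))
  key <- strsplit(col1, ":", fixed = TRUE)
  chrom <- vapply(key, `[`, character(1), 1)
  pos <- suppressWarnings(as.integer(vapply(
    key, function(k) if (length(k) == 2) k[2] else NA_character_, character(1)
  )))
  depth <- suppressWarnings(as.integer(col2))
  bad <- sort(unique(c(bad, which(is.na(pos) | is.na(depth) | pos < 1 | depth < 0))))
  if (length(bad) > 0) {
    pc_abort(sprintf(
      "malformed per-locus depth row at line %d of '%s'", lineno[bad[1]], path
    ), class = "panelcov_bad_row")
  }
  tibble(chrom = chrom, start = pos - 1L, end = pos, depth = depth)
}

parse_depth_bed_rows <- function(fields, lineno, path) {
  nf <- lengths(fields)
  f <- function(i) {
    vapply(fields, function(x) if (length(x) >= i) x[i] else NA_character_, character(1))
  }
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  depth <- suppressWarnings(as.integer(f(4)))
  bad <- which(nf < 4 | is.na(start) | is.na(end) | is.na(depth) |
    start < 0 | start >= end | depth < 0)
  if (length(bad) > 0) {
    pc_abort(sprintf(
      "malformed per-base BED depth row at line %d of '%s'", lineno[bad[1]], path
    ), class = "panelcov_bad_row")
  }
  tibble(chrom = f(1), start = start, end = end, depth = depth)
}

#' Write a depth profile as 4-column per-base BED
#'
#' Zero-depth runs are omitted (absent bases read back as depth 0).
#'
#' @param profile single-sample depth-profile tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(profile, path) {
  stopifnot(length(unique(profile$sample_id)) <= 1)
  out <- profile |>
    filter(.data$depth > 0) |>
    select("chrom", "start", "end", "depth")
  write_bed(out, path)
}

variant_classes <- c("positional", "large_indel_no_coordinate")
pathogenicity_levels <- c("pathogenic", "likely_pathogenic", "VUS", "unknown")

#' Validate a variant catalogue tibble
#'
#' Positional records must carry `chrom` and `pos`;
#' `large_indel_no_coordinate` records must not. Multiple records at the
#' same position (multiallelic positions) are legal and kept distinct.
#'
#' @param variants data frame with columns `variant_id`, `gene`,
#'   `variant_class`, `chrom`, `pos`, `ref`, `alt`, `hgvs_c`,
#'   `pathogenicity`.
#' @return the catalogue as a tibble, in input order.
#' @export
as_variant_catalogue <- function(variants) {
  variants <- as_tibble(variants)
  check_columns(variants, c(
    "variant_id", "gene", "variant_class", "chrom", "pos",
    "ref", "alt", "hgvs_c", "pathogenicity"
  ), "variant catalogue")
  variants$chrom <- as.character(variants$chrom)
  variants$chrom[!is.na(variants$chrom) & variants$chrom == ""] <- NA_character_
  variants$pos <- suppressWarnings(as.integer(variants$pos))

  bad_class <- which(!variants$variant_class %in% variant_classes)
  if (length(bad_class) > 0) {
    pc_abort(sprintf(
      "unknown variant_class '%s' at record %d",
      variants$variant_class[bad_class[1]], bad_class[1]
    ), class = "panelcov_bad_row")
  }
  positional <- variants$variant_class == "positional"
  bad_pos <- which(positional & (is.na(variants$chrom) | is.na(variants$pos)))
  if (length(bad_pos) > 0) {
    pc_abort(sprintf(
      "positional variant '%s' (record %d) lacks chrom/pos",
      variants$variant_id[bad_pos[1]], bad_pos[1]
    ), class = "panelcov_bad_row")
  }
  bad_li <- which(!positional & (!is.na(variants$chrom) | !is.na(variants$pos)))
  if (length(bad_li) > 0) {
    pc_abort(sprintf(
      "large_indel_no_coordinate variant '%s' (record %d) must not carry coordinates",
      variants$variant_id[bad_li[1]], bad_li[1]
    ), class = "panelcov_bad_row")
  }
  bad_path <- which(!variants$pathogenicity %in% pathogenicity_levels)
  if (length(bad_path) > 0) {
    pc_abort(sprintf(
      "unknown pathogenicity '%s' at record %d",
      variants$pathogenicity[bad_path[1]], bad_path[1]
    ), class = "panelcov_bad_row")
  }
  variants
}

#' Read a variant catalogue TSV
#'
#' Nine tab-separated columns with a header: `variant_id`, `gene`,
#' `variant_class` (`positional` or `large_indel_no_coordinate`), `chrom`,
#' `pos` (1-based; empty for coordinate-free records), `ref`, `alt`,
#' `hgvs_c`, `pathogenicity` (`pathogenic`, `likely_pathogenic`, `VUS`,
#' `unknown`). The layout mirrors an HGMD-style export in which large
#' deletions/insertions lack genomic coordinates.
#'
#' @param path TSV path.
#' @return validated catalogue tibble in file order.
#' @export
read_variant_catalogue <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  as_variant_catalogue(df)
}

#' Write a variant catalogue TSV
#'
#' @param variants validated catalogue tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_catalogue <- function(variants, path) {
  out <- as_variant_catalogue(variants)
  out$pos <- ifelse(is.na(out$pos), "", as.character(out$pos))
  out$chrom <- ifelse(is.na(out$chrom), "", out$chrom)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with header: `sample_id`, `depth_path`, and optionally
#' `group` (e.g. `known_SCAD`, `unknown_SCAD`, `other`). Sample ids must be
#' unique. Relative depth paths are resolved against the manifest's
#' directory.
#'
#' @param path TSV path.
#' @return tibble with columns `sample_id`, `depth_path`, `group`.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  check_columns(df, c("sample_id", "depth_path"), "manifest")
  if (!"group" %in% names(df)) df$group <- NA_character_
  if (anyDuplicated(df$sample_id)) {
    pc_abort(sprintf(
      "duplicated sample_id in manifest: '%s'",
      df$sample_id[duplicated(df$sample_id)][1]
    ), class = "panelcov_bad_input")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$depth_path)
  df$depth_path[rel] <- file.path(dirname(path), df$depth_path[rel])
  df[, c("sample_id", "depth_path", "group")]
}

#' Write a report table deterministically
#'
#' Rows are sorted by every column left to right; columns whose name starts
#' with `pct` are rounded half-up to 2 decimals. The JSON rendering carries
#' the same (rounded) rows plus a `n_rows` field, so it is a faithful
#' superset of the TSV content. Writing the same report twice yields
#' byte-identical files.
#'
#' @param report a data frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  report <- as_tibble(report)
  if (nrow(report) > 0 && ncol(report) > 0) {
    report <- arrange(report, dplyr::pick(dplyr::everything()))
  }
  pct_cols <- grep("^pct", names(report), value = TRUE)
  for (col in pct_cols) report[[col]] <- round_half_up(report[[col]], 2)
  if (format == "tsv") {
    readr::write_tsv(report, path, progress = FALSE)
  } else {
    jsonlite::write_json(
      list(n_rows = nrow(report), data = report),
      path,
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  invisible(path)
}
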