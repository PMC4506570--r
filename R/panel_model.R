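#' Genomic interval and gene-panel plumbing
#'
#' Intervals throughout panelcov follow the BED convention: 0-based,
#' half-open `[start, end)`. Variant and locus positions follow the VCF/HGMD
#' convention: 1-based. Conversion between the two happens only inside
#' [position_in_exon()] and [depth_at()].
#'
#' @name panel-model
NULL

# GRanges is 1-based closed; our tibbles are 0-based half-open.
gr_from_intervals <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Validate a tibble of genomic intervals
#'
#' Checks the `chrom`/`start`/`end` columns and the half-open invariant
#' `0 <= start < end`, naming the first offending record in the error.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return the input, invisibly, as a tibble.
#' @export
validate_intervals <- function(intervals, what = "intervals") {
  intervals <- as_tibble(intervals)
  check_columns(intervals, c("chrom", "start", "end"), what)
  bad <- which(is.na(intervals$start) | is.na(intervals$end) |
    intervals$start < 0 | intervals$start >= intervals$end)
  if (length(bad) > 0) {
    i <- bad[1]
    pc_abort(sprintf(
      "invalid interval in %s at row %d: %s:%s-%s (need 0 <= start < end)",
      what, i, intervals$chrom[i],
      format(intervals$start[i]), format(intervals$end[i])
    ), class = "panelcov_bad_interval")
  }
  invisible(intervals)
}

#' Sort and merge genomic intervals
#'
#' Sorts by (chrom, start) and merges overlapping or bookended (end ==
#' next start) intervals on the same chromosome, preserving the total number
#' of covered bases. Interval names, if present, are dropped: a merged run is
#' no longer any single input record.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return tibble with columns `chrom`, `start`, `end`, sorted, disjoint,
#'   and non-abutting per chromosome.
#' @export
#' @examples
#' normalize_intervals(tibble::tibble(
#'   chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L)
#' ))
normalize_intervals <- function(intervals) {
  intervals <- validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  red <- GenomicRanges::reduce(gr_from_intervals(intervals))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
  arrange(out, .data$chrom, .data$start)
}

#' Overlap in bases between two intervals
#'
#' Vectorised over both intervals. Returns
#' `max(0, min(end_a, end_b) - max(start_a, start_b))` when the chromosomes
#' match, else 0; half-open abutment counts as zero overlap.
#'
#' @param chrom_a,start_a,end_a first interval (0-based half-open).
#' @param chrom_b,start_b,end_b second interval.
#' @return integer vector of overlapping base counts.
#' @export
#' @examples
#' overlap_bases("chr1", 0, 10, "chr1", 5, 8) # 3
#' overlap_bases("chr1", 0, 10, "chr1", 10, 20) # 0
overlap_bases <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  as.integer(ifelse(
    chrom_a == chrom_b,
    pmax(0L, pmin(end_a, end_b) - pmax(start_a, start_b)),
    0L
  ))
}

#' Validate a gene panel
#'
#' A panel is a tibble of exons (`chrom`, `start`, `end`, `exon_id`, `gene`)
#' plus the panel gene list carried as the `genes` attribute. Exon ids must
#' be unique and every exon's gene must appear in the gene list. Overlapping
#' exons (alternate transcripts) are legal and retained as distinct records.
#'
#' @param panel data frame of exons.
#' @param genes optional character vector of panel gene symbols; defaults to
#'   the `genes` attribute of `panel`, or the distinct genes of the exons.
#' @return the panel as a tibble with a `genes` attribute.
#' @export
as_panel <- function(panel, genes = NULL) {
  panel <- as_tibble(panel)
  check_columns(panel, c("chrom", "start", "end", "exon_id", "gene"), "panel")
  validate_intervals(panel, "panel exons")
  if (anyDuplicated(panel$exon_id)) {
    dup <- panel$exon_id[duplicated(panel$exon_id)][1]
    pc_abort(sprintf("duplicated exon_id in panel: '%s'", dup),
      class = "panelcov_bad_input"
    )
  }
  genes <- genes %||% attr(panel, "genes") %||% unique(panel$gene)
  if (anyDuplicated(genes)) {
    pc_abort("panel gene symbols must be unique", class = "panelcov_bad_input")
  }
  stray <- setdiff(unique(panel$gene), genes)
  if (length(stray) > 0) {
    pc_abort(sprintf(
      "exon gene(s) not in the panel gene list: %s",
      paste(stray, collapse = ", ")
    ), class = "panelcov_bad_input")
  }
  attr(panel, "genes") <- genes
  panel
}

#' Panel gene list
#'
#' @param panel a panel tibble from [as_panel()] or [read_panel_bed()].
#' @return character vector of gene symbols.
#' @export
panel_genes <- function(panel) {
  attr(panel, "genes") %||% unique(panel$gene)
}

#' Exons containing a 1-based position
#'
#' Converts the position to 0-based and returns the `exon_id` of every exon
#' whose half-open interval contains it; `character(0)` if none. The first
#' base of an exon `[start, end)` is position `start + 1` in 1-based
#' coordinates, so `pos1 == start` is outside the exon.
#'
#' @param chrom chromosome name.
#' @param pos1 1-based position (scalar).
#' @param panel panel tibble of exons.
#' @return character vector of exon ids.
#' @export
position_in_exon <- function(chrom, pos1, panel) {
  stopifnot(length(chrom) == 1, length(pos1) == 1, pos1 >= 1)
  hit <- panel$chrom == chrom & panel$start <= (pos1 - 1) & (pos1 - 1) < panel$end
  panel$exon_id[hit]
}

#' Join 1-based positions to the exons containing them
#'
#' The tidy, vectorised companion of [position_in_exon()]: one output row
#' per (position, containing exon) pair. Positions contained in no exon are
#' absent from the result.
#'
#' @param positions data frame with columns `chrom`, `pos` (1-based).
#' @param panel panel tibble of exons.
#' @return tibble with the position columns plus `exon_id` and `gene`.
#' @export
join_positions_exons <- function(positions, panel) {
  positions <- as_tibble(positions)
  check_columns(positions, c("chrom", "pos"), "positions")
  if (nrow(positions) == 0 || nrow(panel) == 0) {
    return(mutate(positions[0, ], exon_id = character(), gene = character()))
  }
  pos_gr <- GenomicRanges::GRanges(
    seqnames = positions$chrom,
    ranges = IRanges::IRanges(start = positions$pos, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(pos_gr, gr_from_intervals(panel))
  tibble(
    positions[S4Vectors::queryHits(hits), ],
    exon_id = panel$exon_id[S4Vectors::subjectHits(hits)],
    gene = panel$gene[S4Vectors::subjectHits(hits)]
  )
}

#' Read a panel exon BED file
#'
#' Tab-separated BED, 0-based half-open. Column 4 is the exon id and
#' column 5 (if present) the gene symbol; with only 4 columns the gene is
#' parsed from an id of the form `GENE_exonN`, and with 3 columns ids are
#' generated. A gene list supplied via `genes` (or `genes_file`) becomes the
#' panel membership list.
#'
#' @param path BED file path.
#' @param genes optional character vector of panel gene symbols.
#' @param genes_file optional path to a one-symbol-per-line gene list file.
#' @return a panel tibble (see [as_panel()]).
#' @export
read_panel_bed <- function(path, genes = NULL, genes_file = NULL) {
  raw <- read_bed(path, max_cols = 5)
  n <- ncol(raw)
  exon_id <- if (n >= 4) as.character(raw[[4]]) else sprintf("exon%06d", seq_len(nrow(raw)))
  gene <- if (n >= 5) {
    as.character(raw[[5]])
  } else {
    sub("_.*$", "", exon_id)
  }
  if (!is.null(genes_file)) {
    genes <- readr::read_lines(genes_file)
    genes <- genes[nzchar(trimws(genes))]
  }
  as_panel(
    tibble(
      chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]]), exon_id = exon_id, gene = gene
    ),
    genes = genes
  )
}

#' Read a capture design BED file and normalize it
#'
#' @param path BED file path (3+ columns; extra columns ignored).
#' @return normalized target tibble (`chrom`, `start`, `end`), merged and
#'   sorted per [normalize_intervals()].
#' @export
read_design_bed <- function(path) {
  raw <- read_bed(path, max_cols = 3)
  normalize_intervals(tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  ))
}

# shared minimal BED reader: tab-separated, no header, up to max_cols columns
read_bed <- function(path, max_cols) {
  raw <- utils::read.table(path,
    sep = "\t", header = FALSE, colClasses = "character",
    comment.char = "#", quote = "", stringsAsFactors = FALSE,
    blank.lines.skip = TRUE
  )
  if (ncol(raw) < 3) {
    pc_abort(sprintf("BED file '%s' has fewer than 3 columns", path),
      class = "panelcov_bad_input"
    )
  }
  raw[, seq_len(min(ncol(raw), max_cols)), drop = FALSE]
}

#' Write intervals as BED
#'
#' Deterministic writer used by the generators: rows ordered by
#' (chrom, start, end), tab-separated, no header.
#'
#' @param df data frame with `chrom`, `start`, `end` and optionally further
#'   columns (written in order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  df <- arrange(as_tibble(df), .data$chrom, .data$start, .data$end)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Bundled gene list of the 103-gene sudden cardiac arrest/death panel
#'
#' Returns the curated list of 103 gene symbols associated with sudden
#' cardiac arrest/death (SCA/D) used as the package's reference panel gene
#' list, shipped as a plain-text fixture.
#'
#' @return character vector of 103 gene symbols.
#' @export
scad_panel_genes <- function() {
  path <- system.file("extdata", "scad_panel_genes.txt", package = "panelcov")
  genes <- readr::read_lines(path)
  genes[nzchar(trimws(genes))]
}
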