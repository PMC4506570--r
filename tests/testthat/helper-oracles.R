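# Brute-force oracles, deliberately naive: every one of them enumerates
# bases or records one at a time and is used only to cross-check the
# interval-algebra implementations on small fixtures.

# set of covered bases as "chrom:pos0" strings
oracle_base_set <- function(intervals) {
  out <- character(0)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$end[i] > intervals$start[i]) {
      out <- c(out, paste0(
        intervals$chrom[i], ":",
        seq(intervals$start[i], intervals$end[i] - 1L)
      ))
    }
  }
  unique(out)
}

# exon ids containing a 1-based position, by per-base scan
oracle_position_exons <- function(chrom, pos1, panel) {
  hits <- character(0)
  for (i in seq_len(nrow(panel))) {
    if (panel$chrom[i] != chrom) next
    for (b in seq(panel$start[i], panel$end[i] - 1L)) {
      if (b == pos1 - 1L) hits <- c(hits, panel$exon_id[i])
    }
  }
  hits
}

# per-base depth lookup against an expanded run table
oracle_expand_profile <- function(profile) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(profile))) {
    for (b in seq(profile$start[i], profile$end[i] - 1L)) {
      assign(paste0(profile$chrom[i], ":", b), profile$depth[i], envir = env)
    }
  }
  env
}

oracle_depth_at <- function(expanded, chrom, pos1) {
  key <- paste0(chrom, ":", pos1 - 1L)
  if (exists(key, envir = expanded)) get(key, envir = expanded) else 0L
}

# covered-at-threshold base count of one exon, per-base
oracle_covered_count <- function(expanded, exon, d) {
  n <- 0L
  for (b in seq(exon$start, exon$end - 1L)) {
    if (oracle_depth_at(expanded, exon$chrom, b + 1L) >= d) n <- n + 1L
  }
  n
}

# catalogue partition by explicit grouping
oracle_partition <- function(variants) {
  pos <- variants[variants$variant_class == "positional", ]
  key <- paste0(pos$chrom, ":", pos$pos)
  tab <- table(key)
  list(
    n_total = nrow(variants),
    n_large_indel = nrow(variants) - nrow(pos),
    n_positional = nrow(pos),
    n_unique_positions = length(tab),
    n_multiallelic_positions = sum(tab >= 2)
  )
}

# depth binning by explicit comparison chain
oracle_bin <- function(depth, d) {
  vapply(depth, function(x) {
    if (x >= d) {
      "ADEQUATE"
    } else if (x >= 10) {
      "MID"
    } else if (x >= 5) {
      "LOW"
    } else {
      "VERY_LOW"
    }
  }, character(1))
}

# random interval fixture on a handful of chromosomes
random_intervals <- function(n, max_pos = 500, chroms = c("chrA", "chrB")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(30, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len
  )
}

# small panel with overlapping exons allowed
random_panel <- function(n_exons = 20, max_pos = 400, chroms = c("chrA", "chrB")) {
  iv <- random_intervals(n_exons, max_pos, chroms)
  as_panel(tibble::tibble(
    iv,
    exon_id = sprintf("G%d_exon%03d", (seq_len(n_exons) - 1) %% 4 + 1, seq_len(n_exons)),
    gene = sprintf("G%d", (seq_len(n_exons) - 1) %% 4 + 1)
  ))
}

# random single-sample depth profile over a panel
random_profile <- function(panel, sample_id = "S1", max_depth = 40) {
  fp <- panel_footprint(panel)
  runs <- list()
  for (i in seq_len(nrow(fp))) {
    w <- fp$end[i] - fp$start[i]
    cuts <- sort(unique(c(0L, sample.int(w, min(3, w)), w)))
    for (j in seq_len(length(cuts) - 1)) {
      runs[[length(runs) + 1]] <- tibble::tibble(
        chrom = fp$chrom[i],
        start = fp$start[i] + cuts[j],
        end = fp$start[i] + cuts[j + 1],
        depth = sample.int(max_depth + 1, 1) - 1L
      )
    }
  }
  as_depth_profile(dplyr::bind_rows(runs), panel, sample_id)
}

# small catalogue builder
make_catalogue <- function(n_unique, n_multi, n_large_indel,
                           chrom = "chrA", start_pos = 1L,
                           pathogenicity = "pathogenic", gene = "G1") {
  stopifnot(n_multi <= n_unique)
  pos <- seq.int(start_pos, length.out = n_unique)
  rec <- tibble::tibble(
    gene = gene, variant_class = "positional",
    chrom = chrom, pos = as.integer(c(pos, pos[seq_len(n_multi)])),
    ref = "A", alt = c(rep("C", n_unique), rep("G", n_multi))
  )
  li <- tibble::tibble(
    gene = gene, variant_class = "large_indel_no_coordinate",
    chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
    alt = NA_character_
  )[rep(1, n_large_indel), ]
  out <- dplyr::bind_rows(rec, li)
  out$variant_id <- sprintf("v%05d", seq_len(nrow(out)))
  out$hgvs_c <- "c.1A>C"
  out$pathogenicity <- pathogenicity
  as_variant_catalogue(out)
}
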