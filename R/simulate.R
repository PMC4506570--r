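#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions the pipeline is meant to analyse: a 103-gene panel
#' with 2,190 exons, a capture design dropping 2.4% of exons, 72 samples, a
#' 20x adequacy threshold, the five-tier category mixture
#' (81 / 5.04 / 4.91 / 3.39 / 5.66 %), and an 11,452-record variant
#' catalogue of which 16.6% are coordinate-free large indels and 11.4% of
#' unique positions are multiallelic (two records each). Exon lengths
#' (60-300 bp), intergenic gaps, the stochastic depth model, and the
#' pathogenicity mixture are field-realistic choices documented in the
#' methods vignette.
#'
#' All output is a deterministic function of (config, seed): each generator
#' stage derives its RNG stream from `seed` plus a fixed stage offset.
#'
#' @param seed base random seed (integer).
#' @param n_genes number of panel genes. Up to 103 genes reuse the bundled
#'   SCA/D symbols; beyond that synthetic symbols are generated.
#' @param n_exons_total total exon count across the panel.
#' @param exons_per_gene length-2 range of relative per-gene exon weights.
#' @param exon_length length-2 integer range of exon lengths (>= 20).
#' @param intergap length-2 integer range of gaps between neighbouring exons.
#' @param chrom_length synthetic chromosome length; layouts exceeding it are
#'   an error (infeasible geometry).
#' @param p_nc capture dropout probability per exon, in `[0, 1)`.
#' @param target_trim bases trimmed from each end of a captured exon's
#'   target.
#' @param n_samples number of samples.
#' @param depth_threshold adequacy threshold in reads.
#' @param category_mixture named 5-vector of planted category probabilities
#'   (`FULL`, `WELL`, `MOSTLY`, `LIGHT`, `NONE`), summing to 1.
#' @param depth_mean named 2-vector of negative-binomial mean depths for the
#'   stochastic model: `on` for an exon's well-captured core, `off` for its
#'   poorly captured edges.
#' @param nb_size named 2-vector of negative-binomial size (inverse
#'   overdispersion) parameters: `FULL` exons use the tighter `FULL` size so
#'   that no core base dips below threshold; all other tiers use `other`.
#' @param target_fraction named 5-vector of per-category target covered
#'   fractions: in stochastic mode this fraction of an exon's bases forms
#'   the well-captured core, the rest fall off at the edges.
#' @param n_variants catalogue size.
#' @param frac_large_indel fraction of records that are coordinate-free
#'   large indels.
#' @param frac_multiallelic fraction of unique positions carrying two
#'   records.
#' @param pathogenicity_mixture named 4-vector over
#'   pathogenic / likely_pathogenic / VUS / unknown, summing to 1.
#' @param n_cases diagnostic cohort size for the findings generator.
#' @param verdict_mixture named 3-vector of planted verdict probabilities
#'   (`positive`, `uncertain`, `negative`), summing to 1.
#' @return an object of class `panelcov_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 103L,
                       n_exons_total = 2190L,
                       exons_per_gene = c(5, 40),
                       exon_length = c(60L, 300L),
                       intergap = c(100L, 2000L),
                       chrom_length = 5e6,
                       p_nc = 0.024,
                       target_trim = 0L,
                       n_samples = 72L,
                       depth_threshold = 20L,
                       category_mixture = c(
                         FULL = 0.81, WELL = 0.0504, MOSTLY = 0.0491,
                         LIGHT = 0.0339, NONE = 0.0566
                       ),
                       depth_mean = c(on = 100, off = 2),
                       nb_size = c(FULL = 50, other = 8),
                       target_fraction = c(
                         FULL = 1.0, WELL = 0.95, MOSTLY = 0.80,
                         LIGHT = 0.55, NONE = 0.15
                       ),
                       n_variants = 11452L,
                       frac_large_indel = 1896 / 11452,
                       frac_multiallelic = 978 / 8578,
                       pathogenicity_mixture = c(
                         pathogenic = 0.5, likely_pathogenic = 0.2,
                         VUS = 0.2, unknown = 0.1
                       ),
                       n_cases = 30L,
                       verdict_mixture = c(
                         positive = 5 / 30, uncertain = 16 / 30, negative = 9 / 30
                       )) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_exons_total = as.integer(n_exons_total),
    exons_per_gene = exons_per_gene, exon_length = as.integer(exon_length),
    intergap = as.integer(intergap), chrom_length = chrom_length,
    p_nc = p_nc, target_trim = as.integer(target_trim),
    n_samples = as.integer(n_samples),
    depth_threshold = as.integer(depth_threshold),
    category_mixture = category_mixture,
    depth_mean = depth_mean, nb_size = nb_size,
    target_fraction = target_fraction,
    n_variants = as.integer(n_variants),
    frac_large_indel = frac_large_indel,
    frac_multiallelic = frac_multiallelic,
    pathogenicity_mixture = pathogenicity_mixture,
    n_cases = as.integer(n_cases), verdict_mixture = verdict_mixture
  )
  stopifnot(
    cfg$n_genes >= 1, cfg$n_exons_total >= cfg$n_genes,
    cfg$exon_length[1] >= 20, cfg$exon_length[1] <= cfg$exon_length[2],
    cfg$p_nc >= 0, cfg$p_nc < 1, cfg$target_trim >= 0,
    cfg$n_samples >= 1, cfg$depth_threshold >= 1,
    cfg$frac_large_indel >= 0, cfg$frac_large_indel < 1,
    cfg$frac_multiallelic >= 0, cfg$frac_multiallelic < 1
  )
  check_mixture <- function(x, nm, levels) {
    if (!setequal(names(x), levels) || any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      pc_abort(sprintf(
        "%s must be a non-negative vector named %s summing to 1",
        nm, paste(levels, collapse = "/")
      ), class = "panelcov_bad_input")
    }
  }
  check_mixture(cfg$category_mixture, "category_mixture", coverage_categories())
  check_mixture(
    cfg$pathogenicity_mixture, "pathogenicity_mixture", pathogenicity_levels
  )
  check_mixture(
    cfg$verdict_mixture, "verdict_mixture", c("positive", "uncertain", "negative")
  )
  structure(cfg, class = "panelcov_sim_config")
}

# stage offsets for derived RNG streams
sim_seed <- function(cfg, stage) {
  offsets <- c(panel = 11L, capture = 23L, depth = 37L, variants = 53L, findings = 71L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

# largest-remainder apportionment of `total` into counts proportional to w,
# each at least 1
apportion <- function(w, total) {
  stopifnot(total >= length(w))
  raw <- w / sum(w) * total
  counts <- pmax(1L, floor(raw))
  while (sum(counts) > total) {
    i <- which(counts > 1)[which.max(counts[counts > 1] - raw[counts > 1])]
    counts[i] <- counts[i] - 1L
  }
  while (sum(counts) < total) {
    i <- which.max(raw - counts)
    counts[i] <- counts[i] + 1L
  }
  as.integer(counts)
}

#' Generate a synthetic gene panel
#'
#' Lays each gene on its own synthetic chromosome (`chrS1`, `chrS2`, ...)
#' as non-overlapping exons with random lengths and gaps; the total exon
#' count equals `n_exons_total` exactly.
#'
#' @param config a [sim_config()].
#' @return a panel tibble (see [as_panel()]).
#' @export
sim_panel <- function(config) {
  cfg <- config
  with_seed(sim_seed(cfg, "panel"), {
    genes <- if (cfg$n_genes <= 103) {
      scad_panel_genes()[seq_len(cfg$n_genes)]
    } else {
      sprintf("GENE%04d", seq_len(cfg$n_genes))
    }
    n_ex <- apportion(
      runif(cfg$n_genes, cfg$exons_per_gene[1], cfg$exons_per_gene[2]),
      cfg$n_exons_total
    )
    rows <- purrr::map2(seq_len(cfg$n_genes), n_ex, function(g, k) {
      lens <- sample(cfg$exon_length[1]:cfg$exon_length[2], k, replace = TRUE)
      gaps <- sample(cfg$intergap[1]:cfg$intergap[2], k, replace = TRUE)
      start <- cumsum(gaps) + c(0L, cumsum(lens)[-k])
      tibble(
        chrom = sprintf("chrS%d", g),
        start = as.integer(start),
        end = as.integer(start + lens),
        exon_id = sprintf("%s_exon%03d", genes[g], seq_len(k)),
        gene = genes[g]
      )
    })
    panel <- bind_rows(rows)
    if (any(panel$end > cfg$chrom_length)) {
      pc_abort("infeasible geometry: exon layout exceeds chromosome length",
        class = "panelcov_bad_input"
      )
    }
    as_panel(panel, genes = genes)
  })
}

#' Generate a capture design with exon dropout
#'
#' Each exon's target is included with probability `1 - p_nc` and trimmed
#' by `target_trim` bases at each end (kept at least 1 base wide). The
#' dropped exon ids are emitted as ground truth.
#'
#' @param panel panel tibble from [sim_panel()].
#' @param config a [sim_config()].
#' @return list with `design` (normalized target tibble) and
#'   `dropped_exon_ids` (character vector, possibly empty).
#' @export
sim_capture <- function(panel, config) {
  cfg <- config
  with_seed(sim_seed(cfg, "capture"), {
    dropped <- runif(nrow(panel)) < cfg$p_nc
    kept <- panel[!dropped, , drop = FALSE]
    trim <- cfg$target_trim
    start <- kept$start + trim
    end <- kept$end - trim
    too_small <- start >= end
    mid <- (kept$start + kept$end) %/% 2L
    start[too_small] <- mid[too_small]
    end[too_small] <- mid[too_small] + 1L
    design <- normalize_intervals(tibble(
      chrom = kept$chrom, start = as.integer(start), end = as.integer(end)
    ))
    list(design = design, dropped_exon_ids = panel$exon_id[dropped])
  })
}

# admissible integer counts of at-threshold bases for a category of an
# L-base exon (category boundaries are on the fraction n/L)
category_count_range <- function(category, L, breaks = c(0.40, 0.70, 0.90)) {
  L <- rep_len(as.integer(L), length(category))
  lo <- c(NONE = 0, LIGHT = breaks[1], MOSTLY = breaks[2], WELL = breaks[3], FULL = 1)
  hi <- c(NONE = breaks[1], LIGHT = breaks[2], MOSTLY = breaks[3], WELL = 1, FULL = 1)
  n_lo <- as.integer(ceiling(lo[category] * L))
  n_hi <- as.integer(ceiling(hi[category] * L)) - 1L
  n_hi[category == "FULL"] <- L[category == "FULL"]
  cbind(n_lo, pmin(n_hi, L))
}

#' Generate per-sample depth profiles with planted coverage categories
#'
#' Per sample, every captured exon is assigned a category from the
#' configured mixture; non-captured exons get depth 0 throughout and no
#' planted category.
#'
#' In **exact** mode the assigned category is planted literally: an integer
#' count of at-threshold bases is drawn uniformly from the category's
#' admissible range, the first `n` bases of the exon get depth
#' `5 * depth_threshold` and the rest `depth_threshold - 1`, so the
#' classifier must recover the planted category exactly. In **stochastic**
#' mode the category's target fraction of the exon forms a well-captured
#' core (negative-binomial depth around `depth_mean["on"]`) while the
#' remaining bases fall off at the exon edges (`depth_mean["off"]`),
#' mimicking the capture-efficiency decay at target boundaries; recovery
#' then holds in distribution rather than exactly.
#'
#' @param panel panel tibble from [sim_panel()].
#' @param capture list from [sim_capture()].
#' @param config a [sim_config()].
#' @param mode `"exact"` or `"stochastic"`.
#' @return list with `profiles` (multi-sample depth-profile tibble) and
#'   `truth` (tibble `sample_id`, `exon_id`, `category`; `NA` category for
#'   non-captured exons).
#' @export
sim_depths <- function(panel, capture, config, mode = c("exact", "stochastic")) {
  mode <- match.arg(mode)
  cfg <- config
  d <- cfg$depth_threshold
  cats <- coverage_categories()
  mix <- cfg$category_mixture[cats]
  captured <- !panel$exon_id %in% capture$dropped_exon_ids
  L <- panel$end - panel$start

  # simulated exons never overlap, so the profile can be assembled directly:
  # generated runs over captured exons plus zero runs over dropped ones tile
  # the footprint exactly, with no need for the general clip-and-fill path
  zero_runs <- tibble(
    chrom = panel$chrom[!captured], start = panel$start[!captured],
    end = panel$end[!captured], depth = 0L
  )
  ex <- panel[captured, , drop = FALSE]
  exL <- L[captured]

  with_seed(sim_seed(cfg, "depth"), {
    out <- purrr::map(seq_len(cfg$n_samples), function(s) {
      sid <- sprintf("S%03d", s)
      category <- rep(NA_character_, nrow(panel))
      cat_c <- sample(cats, nrow(ex), replace = TRUE, prob = mix)
      category[captured] <- cat_c
      if (mode == "exact") {
        rng <- category_count_range(cat_c, exL)
        n_hi <- as.integer(floor(runif(nrow(ex), rng[, 1], rng[, 2] + 1)))
        n_hi <- pmin(n_hi, rng[, 2]) # guard the open upper edge of runif
        hi <- tibble(
          chrom = ex$chrom, start = ex$start,
          end = ex$start + n_hi, depth = 5L * d
        )
        lo <- tibble(
          chrom = ex$chrom, start = ex$start + n_hi,
          end = ex$end, depth = d - 1L
        )
        runs <- bind_rows(
          filter(hi, .data$end > .data$start),
          filter(lo, .data$end > .data$start)
        )
      } else {
        size <- ifelse(cat_c == "FULL", cfg$nb_size[["FULL"]], cfg$nb_size[["other"]])
        k <- as.integer(round(cfg$target_fraction[cat_c] * exL))
        left <- (exL - k) %/% 2L
        right <- exL - k - left
        # per-base means: well-captured core of k bases, falloff at the edges
        seg_len <- as.vector(rbind(left, k, right))
        seg_mu <- rep(
          c(cfg$depth_mean[["off"]], cfg$depth_mean[["on"]], cfg$depth_mean[["off"]]),
          nrow(ex)
        )
        depths <- as.integer(rnbinom(sum(exL),
          size = rep(size, exL), mu = rep(seg_mu, seg_len)
        ))
        idx <- rep(seq_len(nrow(ex)), exL)
        pos0 <- sequence(exL, from = ex$start) # 0-based base coordinates
        # vectorised run-length encoding: a new run starts at every depth
        # change or exon boundary
        n <- length(depths)
        new_run <- c(TRUE, depths[-1] != depths[-n] | idx[-1] != idx[-n])
        starts <- which(new_run)
        ends <- c(starts[-1] - 1L, n)
        runs <- tibble(
          chrom = ex$chrom[idx[starts]],
          start = pos0[starts],
          end = pos0[ends] + 1L,
          depth = depths[starts]
        )
      }
      profile <- tibble(sample_id = sid, bind_rows(runs, zero_runs)) |>
        arrange(.data$chrom, .data$start)
      list(
        profile = profile,
        truth = tibble(
          sample_id = sid, exon_id = panel$exon_id, category = category
        )
      )
    })
    list(
      profiles = bind_rows(purrr::map(out, "profile")),
      truth = bind_rows(purrr::map(out, "truth"))
    )
  })
}

#' Generate a variant catalogue with known partition
#'
#' Unique positions are sampled uniformly without replacement over the panel
#' exon footprint; a configured fraction of them receive a second record
#' with a different alternate allele (multiallelic positions); large-indel
#' records carry no coordinates. The realized partition is emitted as ground
#' truth.
#'
#' @param panel panel tibble from [sim_panel()].
#' @param config a [sim_config()].
#' @return list with `variants` (catalogue tibble) and `truth` (one-row
#'   tibble of partition counts).
#' @export
sim_variants <- function(panel, config) {
  cfg <- config
  fp <- panel_footprint(panel)
  widths <- fp$end - fp$start
  total_bases <- sum(widths)

  n_li <- as.integer(round(cfg$frac_large_indel * cfg$n_variants))
  n_positional <- cfg$n_variants - n_li
  n_unique <- as.integer(round(n_positional / (1 + cfg$frac_multiallelic)))
  n_multi <- n_positional - n_unique
  if (n_multi > n_unique) {
    pc_abort("frac_multiallelic implies more duplicate records than positions",
      class = "panelcov_bad_input"
    )
  }
  if (n_unique > total_bases) {
    pc_abort(sprintf(
      "requested %d unique positions exceed the %d available exon bases",
      n_unique, total_bases
    ), class = "panelcov_bad_input")
  }

  with_seed(sim_seed(cfg, "variants"), {
    base_idx <- sort(sample.int(total_bases, n_unique))
    iv <- findInterval(base_idx - 1L, cumsum(c(0L, widths)))
    pos0 <- fp$start[iv] + (base_idx - 1L - cumsum(c(0L, widths))[iv])
    upos <- tibble(chrom = fp$chrom[iv], pos = as.integer(pos0 + 1L))

    gene_of <- join_positions_exons(upos, panel) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE)
    upos <- left_join(upos, select(gene_of, "chrom", "pos", "gene"),
      by = c("chrom", "pos")
    )
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_unique, replace = TRUE)
    alt1 <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

    rec1 <- tibble(
      gene = upos$gene, variant_class = "positional",
      chrom = upos$chrom, pos = upos$pos, ref = ref, alt = alt1
    )
    multi_at <- if (n_multi > 0) sort(sample.int(n_unique, n_multi)) else integer(0)
    alt2 <- vapply(seq_along(multi_at), function(i) {
      sample(setdiff(bases, c(ref[multi_at[i]], alt1[multi_at[i]])), 1)
    }, character(1))
    rec2 <- tibble(
      gene = upos$gene[multi_at], variant_class = "positional",
      chrom = upos$chrom[multi_at], pos = upos$pos[multi_at],
      ref = ref[multi_at], alt = alt2
    )
    li <- tibble(
      gene = sample(panel_genes(panel), n_li, replace = TRUE),
      variant_class = "large_indel_no_coordinate",
      chrom = NA_character_, pos = NA_integer_,
      ref = NA_character_, alt = NA_character_
    )
    variants <- bind_rows(rec1, rec2, li) |>
      mutate(
        variant_id = sprintf("var%06d", row_number()),
        hgvs_c = ifelse(is.na(.data$pos), "c.?_del",
          sprintf("c.%d%s>%s", .data$pos, .data$ref, .data$alt)
        ),
        pathogenicity = sample(
          pathogenicity_levels, n(),
          replace = TRUE, prob = cfg$pathogenicity_mixture[pathogenicity_levels]
        )
      ) |>
      select(
        "variant_id", "gene", "variant_class", "chrom", "pos",
        "ref", "alt", "hgvs_c", "pathogenicity"
      )
    truth <- tibble(
      n_total = cfg$n_variants, n_large_indel = n_li,
      n_positional = n_positional, n_unique_positions = n_unique,
      n_multiallelic_positions = n_multi
    )
    list(variants = as_variant_catalogue(variants), truth = truth)
  })
}

#' Generate case findings with planted verdicts
#'
#' Verdict counts are apportioned from the verdict mixture (largest
#' remainder), then each case receives findings consistent with its planted
#' verdict: positive cases one pathogenic or likely-pathogenic finding plus
#' possible VUS, uncertain cases one to three VUS, negative cases none.
#'
#' @param panel panel tibble (source of gene symbols).
#' @param config a [sim_config()].
#' @return list with `findings` (tibble `sample_id`, `variant_id`, `gene`,
#'   `pathogenicity`, `zygosity`) and `truth` (tibble `sample_id`,
#'   `verdict`).
#' @export
sim_findings <- function(panel, config) {
  cfg <- config
  with_seed(sim_seed(cfg, "findings"), {
    verdicts <- c("positive", "uncertain", "negative")
    counts <- apportion(cfg$verdict_mixture[verdicts] + 1e-12, cfg$n_cases)
    planted <- sample(rep(verdicts, counts))
    ids <- sprintf("case%03d", seq_len(cfg$n_cases))
    genes <- panel_genes(panel)
    rows <- purrr::map(seq_len(cfg$n_cases), function(i) {
      v <- planted[i]
      if (v == "negative") {
        return(NULL)
      }
      n_vus <- if (v == "uncertain") sample(1:3, 1) else sample(0:2, 1)
      path <- if (v == "positive") {
        sample(c("pathogenic", "likely_pathogenic"), 1)
      } else {
        character(0)
      }
      labs <- c(path, rep("VUS", n_vus))
      tibble(
        sample_id = ids[i],
        gene = sample(genes, length(labs), replace = TRUE),
        pathogenicity = labs,
        zygosity = sample(c("Heterozygous", "Homozygous"), length(labs),
          replace = TRUE, prob = c(0.9, 0.1)
        )
      )
    })
    findings <- bind_rows(rows)
    if (nrow(findings) > 0) {
      findings <- mutate(findings,
        variant_id = sprintf("finding%04d", row_number()),
        .after = "sample_id"
      )
    } else {
      findings <- tibble(
        sample_id = character(), variant_id = character(), gene = character(),
        pathogenicity = character(), zygosity = character()
      )
    }
    list(findings = findings, truth = tibble(sample_id = ids, verdict = planted))
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator and writes the files a real analysis would consume:
#' `panel.bed` (5 columns), `genes.txt`, `design.bed`, per-sample depth BEDs
#' under `depths/`, `manifest.tsv`, `variants.tsv`, `findings.tsv`,
#' `cases.txt` (the diagnostic cohort), plus
#' machine-readable ground truth (`truth_categories.tsv`,
#' `ground_truth.json`). Identical (config, seed) gives byte-identical
#' files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param mode depth mode, `"exact"` or `"stochastic"`.
#' @return invisibly, a list with the generated objects and all file paths.
#' @export
sim_dataset <- function(config, dir, mode = c("exact", "stochastic")) {
  mode <- match.arg(mode)
  cfg <- config
  dir.create(file.path(dir, "depths"), recursive = TRUE, showWarnings = FALSE)

  panel <- sim_panel(cfg)
  capture <- sim_capture(panel, cfg)
  depths <- sim_depths(panel, capture, cfg, mode = mode)
  variants <- sim_variants(panel, cfg)
  findings <- sim_findings(panel, cfg)

  paths <- list(
    panel = file.path(dir, "panel.bed"),
    genes = file.path(dir, "genes.txt"),
    design = file.path(dir, "design.bed"),
    manifest = file.path(dir, "manifest.tsv"),
    variants = file.path(dir, "variants.tsv"),
    findings = file.path(dir, "findings.tsv"),
    cases = file.path(dir, "cases.txt"),
    truth_categories = file.path(dir, "truth_categories.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_bed(panel[, c("chrom", "start", "end", "exon_id", "gene")], paths$panel)
  readr::write_lines(panel_genes(panel), paths$genes)
  write_bed(capture$design, paths$design)

  sample_ids <- sort(unique(depths$profiles$sample_id))
  depth_paths <- file.path("depths", paste0(sample_ids, ".bed"))
  for (i in seq_along(sample_ids)) {
    write_depth_bed(
      filter(depths$profiles, .data$sample_id == sample_ids[i]),
      file.path(dir, depth_paths[i])
    )
  }
  readr::write_tsv(
    tibble(sample_id = sample_ids, depth_path = depth_paths, group = "other"),
    paths$manifest,
    progress = FALSE
  )
  write_variant_catalogue(variants$variants, paths$variants)
  readr::write_tsv(findings$findings, paths$findings, progress = FALSE)
  readr::write_lines(findings$truth$sample_id, paths$cases)
  readr::write_tsv(depths$truth, paths$truth_categories, progress = FALSE)

  planted_props <- depths$truth |>
    filter(!is.na(.data$category)) |>
    group_by(.data$sample_id) |>
    count(category = factor(.data$category,
      levels = coverage_categories(), ordered = TRUE
    ), .drop = FALSE, name = "n_exons") |>
    mutate(proportion = .data$n_exons / sum(.data$n_exons)) |>
    ungroup()
  jsonlite::write_json(
    list(
      mode = mode,
      seed = cfg$seed,
      n_exons = nrow(panel),
      dropped_exon_ids = capture$dropped_exon_ids,
      catalogue_partition = variants$truth,
      planted_category_proportions = planted_props,
      verdicts = findings$truth
    ),
    paths$ground_truth,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    config = cfg, panel = panel, capture = capture, depths = depths,
    variants = variants, findings = findings, paths = paths, dir = dir
  ))
}
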