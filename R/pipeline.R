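#' Pipeline run configuration
#'
#' Collects the file paths and analysis options of a full run. All input
#' files must exist when the pipeline starts.
#'
#' @param panel_bed panel exon BED path.
#' @param design_bed capture design BED path.
#' @param manifest_tsv sample manifest path.
#' @param variants_tsv variant catalogue path.
#' @param genes_txt optional gene list path (one symbol per line); default:
#'   genes present in the panel BED.
#' @param findings_tsv optional case findings path; triage runs only when
#'   given.
#' @param cases_txt optional path listing all case ids of the diagnostic
#'   cohort, one per line; cases absent from the findings file triage
#'   negative. Default: the cases present in the findings file.
#' @param out_dir output directory.
#' @param depth_threshold adequacy threshold in reads.
#' @param min_overlap capture overlap threshold in bases.
#' @param summary_stat `"mean"` or `"median"` summary of per-sample depths.
#' @param denominator `"captured"` or `"all"` exons for category
#'   proportions.
#' @return an object of class `panelcov_run_config`.
#' @export
run_config <- function(panel_bed, design_bed, manifest_tsv, variants_tsv,
                       genes_txt = NULL, findings_tsv = NULL,
                       cases_txt = NULL,
                       out_dir = "panelcov_out",
                       depth_threshold = 20L, min_overlap = 1L,
                       summary_stat = c("mean", "median"),
                       denominator = c("captured", "all")) {
  cfg <- list(
    panel_bed = panel_bed, design_bed = design_bed,
    manifest_tsv = manifest_tsv, variants_tsv = variants_tsv,
    genes_txt = genes_txt, findings_tsv = findings_tsv,
    cases_txt = cases_txt,
    out_dir = out_dir,
    depth_threshold = as.integer(depth_threshold),
    min_overlap = as.integer(min_overlap),
    summary_stat = match.arg(summary_stat),
    denominator = match.arg(denominator)
  )
  required <- c(
    cfg$panel_bed, cfg$design_bed, cfg$manifest_tsv, cfg$variants_tsv,
    cfg$genes_txt, cfg$findings_tsv, cfg$cases_txt
  )
  missing <- required[!file.exists(required)]
  if (length(missing) > 0) {
    pc_abort(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")),
      class = "panelcov_missing_file"
    )
  }
  structure(cfg, class = "panelcov_run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    pc_abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "panelcov_stage_error"
    )
  })
}

#' Run the full capture / coverage / detectability / triage pipeline
#'
#' Executes every stage in order — read inputs, assess capture, partition
#' the catalogue and its positions by capture status, classify per-exon
#' coverage, bin variant detectability, and (when findings are supplied)
#' triage the cohort — writing per-stage TSV reports and a combined JSON
#' report with a provenance block (configuration hash and package version).
#' Re-running with identical inputs yields identical report content; a
#' stage failure aborts naming the stage.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every stage's result object plus
#'   `report` (the combined report list) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "panelcov_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) inform(sprintf(...))

  panel <- run_stage("read_panel", {
    read_panel_bed(cfg$panel_bed, genes_file = cfg$genes_txt)
  })
  design <- run_stage("read_design", read_design_bed(cfg$design_bed))
  manifest <- run_stage("read_manifest", read_manifest(cfg$manifest_tsv))
  variants <- run_stage("read_variants", read_variant_catalogue(cfg$variants_tsv))
  log_msg(
    "read %d exons / %d genes, %d design targets, %d samples, %d variant records",
    nrow(panel), length(panel_genes(panel)), nrow(design), nrow(manifest),
    nrow(variants)
  )

  profiles <- run_stage("read_depths", {
    missing <- manifest$depth_path[!file.exists(manifest$depth_path)]
    if (length(missing) > 0) {
      row <- which(!file.exists(manifest$depth_path))[1]
      pc_abort(sprintf(
        "depth file '%s' for sample '%s' (manifest row %d) not found",
        manifest$depth_path[row], manifest$sample_id[row], row
      ), class = "panelcov_missing_file")
    }
    bind_rows(purrr::map2(
      manifest$depth_path, manifest$sample_id,
      function(p, s) read_depth_table(p, panel, sample_id = s)
    ))
  })

  capture <- run_stage("assess_capture", {
    assess_capture(panel, design, min_overlap = cfg$min_overlap)
  })
  log_msg(
    "capture: %d/%d exons captured (%.1f%%)",
    capture$summary$n_captured, capture$summary$n_exons_total,
    capture$summary$pct_captured
  )

  partition <- run_stage("partition_catalogue", partition_catalogue(variants))
  upos <- partition$positions[, c("chrom", "pos")]
  positions <- run_stage("partition_positions", {
    partition_positions_by_capture(upos, panel, capture)
  })

  scheme <- coverage_scheme(depth_threshold = cfg$depth_threshold)
  coverage <- run_stage("coverage", {
    coverage_summary(profiles, panel, scheme,
      capture = capture, positions = upos, denominator = cfg$denominator
    )
  })

  detect <- run_stage("detectability", {
    detectability(variants, profiles, panel, capture,
      bins = detectability_bins(cfg$depth_threshold),
      summary = cfg$summary_stat
    )
  })

  triage <- NULL
  if (!is.null(cfg$findings_tsv)) {
    triage <- run_stage("triage", {
      findings <- readr::read_tsv(cfg$findings_tsv,
        col_types = readr::cols(.default = readr::col_character()),
        progress = FALSE
      )
      cases <- if (!is.null(cfg$cases_txt)) {
        ids <- readr::read_lines(cfg$cases_txt)
        ids[nzchar(trimws(ids))]
      } else {
        unique(findings$sample_id)
      }
      results <- triage_cases(findings, genes = panel_genes(panel), samples = cases)
      cohort_yield(results)
    })
  }

  paths <- run_stage("write_reports", {
    p <- list(
      capture_exons = file.path(cfg$out_dir, "capture_exons.tsv"),
      exon_coverage = file.path(cfg$out_dir, "exon_coverage.tsv"),
      proportions = file.path(cfg$out_dir, "category_proportions.tsv"),
      detectability = file.path(cfg$out_dir, "detectability.tsv"),
      report = file.path(cfg$out_dir, "report.json")
    )
    write_report(capture$exons, p$capture_exons, "tsv")
    write_report(
      mutate(coverage$stats, category = as.character(.data$category)),
      p$exon_coverage, "tsv"
    )
    write_report(
      mutate(coverage$proportions, category = as.character(.data$category)),
      p$proportions, "tsv"
    )
    write_report(
      mutate(detect$records, bin = as.character(.data$bin)),
      p$detectability, "tsv"
    )
    if (!is.null(triage)) {
      p$triage <- file.path(cfg$out_dir, "triage.tsv")
      write_report(
        mutate(triage$yield, verdict = as.character(.data$verdict)),
        p$triage, "tsv"
      )
    }
    p
  })

  report <- list(
    provenance = list(
      package = "panelcov",
      version = as.character(utils::packageVersion("panelcov")),
      # hash of the analysis inputs and options; the output location does
      # not change what was computed
      config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
      depth_threshold = cfg$depth_threshold,
      min_overlap = cfg$min_overlap,
      summary_stat = cfg$summary_stat,
      denominator = cfg$denominator
    ),
    capture = capture$summary,
    catalogue_partition = partition$summary,
    position_partition = positions$summary,
    mean_category_proportions = mutate(coverage$mean_proportions,
      category = as.character(.data$category)
    ),
    none_positions = coverage$none_positions$summary,
    detectability = list(
      bins = mutate(detect$bin_counts, bin = as.character(.data$bin)),
      summary = detect$summary
    ),
    triage = if (!is.null(triage)) triage$yield
  )
  jsonlite::write_json(report, paths$report,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(list(
    panel = panel, design = design, manifest = manifest, profiles = profiles,
    capture = capture, partition = partition, positions = positions,
    coverage = coverage, detectability = detect, triage = triage,
    report = report, paths = paths
  ))
}
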