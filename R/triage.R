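#' Triage cases from their panel-gene findings
#'
#' Applies the clinical-reporting rule at case level:
#' * **positive** — any finding classified `pathogenic` or
#'   `likely_pathogenic`;
#' * **uncertain** — otherwise, any finding classified `VUS`;
#' * **negative** — no pathogenic, likely pathogenic, or VUS finding (a case
#'   with no findings at all is negative).
#'
#' Findings in genes outside the panel are a contract violation and abort.
#'
#' @param findings data frame with columns `sample_id`, `gene`,
#'   `pathogenicity` (plus any others, e.g. `variant_id`, `zygosity`,
#'   carried through untouched). May be empty.
#' @param genes character vector of panel gene symbols (e.g.
#'   [scad_panel_genes()] or [panel_genes()]).
#' @param samples optional character vector of all case ids in the cohort;
#'   cases without findings verdict `negative`. Defaults to the samples
#'   present in `findings`.
#' @return tibble: `sample_id`, `verdict` (factor
#'   `negative < uncertain < positive`).
#' @export
#' @examples
#' findings <- tibble::tibble(
#'   sample_id = c("A", "B", "B"), gene = c("SCN5A", "KCNQ1", "TTN"),
#'   pathogenicity = c("pathogenic", "VUS", "VUS")
#' )
#' triage_cases(findings, genes = c("SCN5A", "KCNQ1", "TTN"), samples = c("A", "B", "C"))
triage_cases <- function(findings, genes, samples = NULL) {
  findings <- as_tibble(findings)
  check_columns(findings, c("sample_id", "gene", "pathogenicity"), "findings")
  stray <- setdiff(unique(findings$gene), genes)
  if (length(stray) > 0) {
    pc_abort(sprintf(
      "finding gene(s) not in the panel: %s", paste(stray, collapse = ", ")
    ), class = "panelcov_bad_input")
  }
  bad <- which(!findings$pathogenicity %in% pathogenicity_levels)
  if (length(bad) > 0) {
    pc_abort(sprintf(
      "unknown pathogenicity '%s' at finding %d",
      findings$pathogenicity[bad[1]], bad[1]
    ), class = "panelcov_bad_row")
  }
  samples <- samples %||% unique(findings$sample_id)
  per_case <- findings |>
    group_by(.data$sample_id) |>
    summarise(
      any_path = any(.data$pathogenicity %in% c("pathogenic", "likely_pathogenic")),
      any_vus = any(.data$pathogenicity == "VUS"),
      .groups = "drop"
    )
  tibble(sample_id = samples) |>
    left_join(per_case, by = "sample_id") |>
    mutate(
      verdict = factor(
        ifelse(dplyr::coalesce(.data$any_path, FALSE), "positive",
          ifelse(dplyr::coalesce(.data$any_vus, FALSE), "uncertain", "negative")
        ),
        levels = c("negative", "uncertain", "positive"), ordered = TRUE
      )
    ) |>
    select("sample_id", "verdict")
}

#' Diagnostic yield of a triaged cohort
#'
#' Counts and percentage shares of the three verdicts. Display percentages
#' are half-up integers (mirroring the usual "17 % / 53 % / 30 %" style of
#' yield reporting); the exact fractions are kept alongside.
#'
#' @param results tibble from [triage_cases()].
#' @return an object of class `panelcov_yield`: list with
#'   * `yield` — tibble `verdict`, `n`, `fraction`, `pct`;
#'   * `n_cases` — cohort size.
#' @export
cohort_yield <- function(results) {
  results <- as_tibble(results)
  check_columns(results, c("sample_id", "verdict"), "triage results")
  if (nrow(results) == 0) {
    pc_abort("cannot compute yield of an empty cohort", class = "panelcov_bad_input")
  }
  yield <- results |>
    count(verdict = factor(.data$verdict,
      levels = c("negative", "uncertain", "positive"), ordered = TRUE
    ), .drop = FALSE, name = "n") |>
    mutate(
      fraction = .data$n / nrow(results),
      pct = round_half_up(100 * .data$fraction, 0)
    ) |>
    arrange(dplyr::desc(.data$verdict))
  structure(list(yield = yield, n_cases = nrow(results)), class = "panelcov_yield")
}

#' @export
print.panelcov_yield <- function(x, ...) {
  cat(sprintf("<panelcov_yield> %d cases\n", x$n_cases))
  cat(paste(
    sprintf(
      "  %-9s %3d/%d (%d%%)", x$yield$verdict, x$yield$n, x$n_cases,
      x$yield$pct
    ),
    collapse = "\n"
  ), "\n")
  invisible(x)
}
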