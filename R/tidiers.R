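#' Tidy and glance methods for panelcov result objects
#'
#' Following the broom convention, `tidy()` returns the per-unit table of a
#' result (per exon, per position, per record, per verdict) and `glance()`
#' a one-row summary.
#'
#' @param x a panelcov result object.
#' @param ... unused.
#' @return a tibble.
#' @name panelcov-tidiers
NULL

#' @rdname panelcov-tidiers
#' @method tidy panelcov_capture
#' @export
tidy.panelcov_capture <- function(x, ...) x$exons

#' @rdname panelcov-tidiers
#' @method glance panelcov_capture
#' @export
glance.panelcov_capture <- function(x, ...) x$summary

#' @rdname panelcov-tidiers
#' @method tidy panelcov_positions
#' @export
tidy.panelcov_positions <- function(x, ...) x$positions

#' @rdname panelcov-tidiers
#' @method glance panelcov_positions
#' @export
glance.panelcov_positions <- function(x, ...) x$summary

#' @rdname panelcov-tidiers
#' @method tidy panelcov_coverage
#' @export
tidy.panelcov_coverage <- function(x, ...) x$proportions

#' @rdname panelcov-tidiers
#' @method glance panelcov_coverage
#' @export
glance.panelcov_coverage <- function(x, ...) {
  wide <- x$mean_proportions |>
    mutate(category = paste0("pct_", tolower(as.character(.data$category)))) |>
    select("category", "pct") |>
    tidyr::pivot_wider(names_from = "category", values_from = "pct")
  dplyr::bind_cols(
    tibble(
      n_samples = length(unique(x$proportions$sample_id)),
      depth_threshold = x$scheme$depth_threshold,
      denominator = x$denominator
    ),
    wide
  )
}

#' @rdname panelcov-tidiers
#' @method tidy panelcov_partition
#' @export
tidy.panelcov_partition <- function(x, ...) x$positions

#' @rdname panelcov-tidiers
#' @method glance panelcov_partition
#' @export
glance.panelcov_partition <- function(x, ...) x$summary

#' @rdname panelcov-tidiers
#' @method tidy panelcov_detectability
#' @export
tidy.panelcov_detectability <- function(x, ...) x$records

#' @rdname panelcov-tidiers
#' @method glance panelcov_detectability
#' @export
glance.panelcov_detectability <- function(x, ...) x$summary

#' @rdname panelcov-tidiers
#' @method tidy panelcov_yield
#' @export
tidy.panelcov_yield <- function(x, ...) x$yield

#' @rdname panelcov-tidiers
#' @method glance panelcov_yield
#' @export
glance.panelcov_yield <- function(x, ...) {
  y <- x$yield
  tibble(
    n_cases = x$n_cases,
    n_positive = y$n[y$verdict == "positive"],
    n_uncertain = y$n[y$verdict == "uncertain"],
    n_negative = y$n[y$verdict == "negative"],
    pct_positive = y$pct[y$verdict == "positive"],
    pct_uncertain = y$pct[y$verdict == "uncertain"],
    pct_negative = y$pct[y$verdict == "negative"]
  )
}
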