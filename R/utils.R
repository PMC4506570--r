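#' Round half away from zero
#'
#' Percentage display in reports uses conventional half-up rounding
#' (97.626 -> 97.6 at one decimal, 16.67 -> 17 at zero decimals), not the
#' round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(2.5, 16.666, 97.626), 0)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, half-up rounded
#'
#' @param count numerator count(s).
#' @param total denominator.
#' @param digits decimals to keep (default 1, the convention used in the
#'   capture and catalogue-partition reports).
#' @return numeric percentage(s).
#' @export
pct_of <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}

# stop with a classed panelcov error
pc_abort <- function(msg, class = "panelcov_error", ...) {
  abort(msg, class = c(class, "panelcov_error"), ...)
}

# check that `df` has the named columns; `what` names the object in errors
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    pc_abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "panelcov_bad_input")
  }
  invisible(df)
}

# evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards (so generators are deterministic without clobbering the
# session seed)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
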