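#' Spearman rank correlation for observer validation
#'
#' Direct evaluation of rho = 1 - 6 sum(d^2) / (n^3 - n), where d is the
#' rank difference per observation — the form used to correlate objective
#' slice scores with mean opinion scores. Ties get average ranks; with ties
#' the formula is the standard approximation, documented as such.
#'
#' @param objective Numeric vector (e.g. per-slice total scores).
#' @param subjective Numeric vector of the same length (e.g. MOS on 0-100).
#' @return Correlation in \[-1, 1\]: 1 for identical orderings, -1 for
#'   exactly reversed orderings.
#' @details Requires n >= 3; a constant vector has no defined ranking and
#'   signals an error.
#' @examples
#' spearman_rho(c(0.2, 0.5, 0.9), c(10, 40, 80))   # 1
#' spearman_rho(c(0.2, 0.5, 0.9), c(80, 40, 10))   # -1
#' @export
spearman_rho <- function(objective, subjective) {
  if (length(objective) != length(subjective)) {
    abort("`objective` and `subjective` must have equal length.")
  }
  n <- length(objective)
  if (n < 3L) abort("Need at least 3 observations.")
  if (anyNA(objective) || anyNA(subjective)) abort("Inputs must not contain NA.")
  if (diff(range(objective)) == 0 || diff(range(subjective)) == 0) {
    abort("Constant input: ranks are undefined.")
  }
  d <- rank(objective) - rank(subjective)
  1 - 6 * sum(d^2) / (n^3 - n)
}

#' Condition-level summary table
#'
#' One row per named condition (a scored volume), with the slice count and
#' mean objective total score; when matching subjective per-slice scores are
#' supplied, their mean and the objective-subjective rank correlation are
#' added. Mirrors the usual validation-table layout (condition, n, average
#' objective, average subjective, correlation).
#'
#' @param volumes Named list of `briq_volume` reports.
#' @param subjective Optional named list of numeric vectors, one MOS value
#'   per slice, names matching `volumes`.
#' @return Tibble with columns `condition`, `n_slices`, `mean_objective`,
#'   `mean_subjective`, `rho`.
#' @export
summary_table <- function(volumes, subjective = NULL) {
  if (length(volumes) == 0L) abort("`volumes` must not be empty.")
  if (!all(vapply(volumes, inherits, logical(1), "briq_volume"))) {
    abort("Every element of `volumes` must be a briq_volume.")
  }
  nms <- names(volumes) %||% as.character(seq_along(volumes))
  rows <- purrr::imap(volumes, function(v, nm) {
    qs <- v$per_slice$Q
    subj <- subjective[[nm]]
    tibble(
      condition = nm,
      n_slices = length(qs),
      mean_objective = mean(qs),
      mean_subjective = if (is.null(subj)) NA_real_ else mean(subj),
      rho = if (is.null(subj) || length(qs) < 3L) NA_real_ else
        spearman_rho(qs, subj)
    )
  })
  names(rows) <- NULL
  dplyr::bind_rows(rows)
}
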