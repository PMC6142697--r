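#' Score a single MRI slice
#'
#' Runs the full no-reference quality pipeline on one slice: foreground
#' extraction, min-max rescaling, range-filter contrast extraction with the
#' size-matched window, moment thresholding into the four binary feature
#' images, and the four attribute scores with their weighted total.
#'
#' @param x Numeric matrix of non-negative intensities (the slice).
#' @param window Odd range-filter width; `NULL` (default) applies the
#'   [select_window()] size rule. An explicit value takes precedence.
#' @param weights [quality_weights()] for the total score.
#' @param fg Optional precomputed logical foreground mask; extracted with
#'   [extract_foreground()] when `NULL`.
#' @param moments_over `"foreground"` (default) computes mu_d and mu_c over
#'   foreground pixels only; `"full"` over the whole canvas.
#' @param connectivity Edge-pixel neighbourhood, 4 (default) or 8.
#' @param edge_denominator See [luminance_contrast()].
#' @return A one-row tibble with columns `n_t`, `window`, `mu_d`, `mu_c`,
#'   `q1`, `q2`, `q3`, `q4`, `Q`. Deterministic for fixed input and options.
#' @examples
#' ph <- phantom_generate(phantom_spec(seed = 7))
#' score_slice(ph$slice)
#' @export
score_slice <- function(x, window = NULL, weights = quality_weights(),
                        fg = NULL,
                        moments_over = c("foreground", "full"),
                        connectivity = 4, edge_denominator = FALSE) {
  check_slice(x)
  moments_over <- match.arg(moments_over)
  if (is.null(fg)) fg <- extract_foreground(x) else check_mask(fg, x)
  n_t <- sum(fg)
  if (n_t < 1L) abort("Foreground mask is empty.")
  gray <- rescale_intensity(x)
  if (is.null(window)) window <- select_window(nrow(x), ncol(x))
  con <- local_contrast(gray, window)
  mfg <- if (moments_over == "foreground") fg else NULL
  mu_d <- first_moment(gray, mfg)
  mu_c <- first_moment(con, mfg)
  bf <- binary_features(gray, con, fg, mu_d = mu_d, mu_c = mu_c)
  q1 <- luminance_contrast(bf$FGMG, bf$FCMG, connectivity, edge_denominator)
  q2 <- texture(bf$FGMC, bf$FCMC, connectivity, edge_denominator)
  q3 <- texture_contrast(bf$FGMC, bf$FCMC, fg, n_t)
  q4 <- lightness(bf$FGMG, bf$FCMG, fg, n_t)
  Q <- total_score(q1, q2, q3, q4, weights)
  tibble(
    n_t = n_t, window = as.integer(window), mu_d = mu_d, mu_c = mu_c,
    q1 = q1, q2 = q2, q3 = q3, q4 = q4, Q = Q
  )
}

default_cutoff <- function(sequence_tag) {
  switch(sequence_tag, T1 = 0.40, T2 = 0.45, unknown = 0.40)
}

#' Aggregate per-slice scores into a volume report
#'
#' Volume quality is the arithmetic mean of the per-slice scores; a volume
#' passes when its mean total score reaches the cut-off. The recommended
#' cut-offs are 0.40 for T1-weighted and 0.45 for T2-weighted volumes. The
#' cut-off flags whole volumes only — it does not suggest rejecting
#' individual slices.
#'
#' @param per_slice Tibble of per-slice scores (columns `q1`..`q4`, `Q`,
#'   typically from [score_slice()]), one row per slice.
#' @param cutoff Quality cut-off in \[0, 1\]; defaults by `sequence_tag`.
#' @param sequence_tag `"T1"`, `"T2"` or `"unknown"` (unknown uses the T1
#'   cut-off).
#' @return Object of class `briq_volume`: list with `per_slice` (tibble with
#'   a `slice` index column), `means` (named vector `q1`..`q4`, `Q`),
#'   `cutoff`, `passes`, `sequence_tag`.
#' @export
aggregate_volume <- function(per_slice, cutoff = NULL,
                             sequence_tag = c("unknown", "T1", "T2")) {
  sequence_tag <- match.arg(sequence_tag)
  per_slice <- as_tibble(per_slice)
  if (nrow(per_slice) < 1L) abort("Need at least one slice to aggregate.")
  need <- c("q1", "q2", "q3", "q4", "Q")
  if (!all(need %in% names(per_slice))) {
    abort("`per_slice` must contain columns q1, q2, q3, q4, Q.")
  }
  if (is.null(cutoff)) cutoff <- default_cutoff(sequence_tag)
  if (cutoff < 0 || cutoff > 1) abort("`cutoff` must lie in [0, 1].")
  if (!"slice" %in% names(per_slice)) {
    per_slice <- dplyr::mutate(per_slice, slice = dplyr::row_number(),
                               .before = 1)
  }
  means <- vapply(per_slice[need], mean, numeric(1))
  structure(
    list(per_slice = per_slice, means = means, cutoff = cutoff,
         passes = unname(means["Q"] >= cutoff), sequence_tag = sequence_tag),
    class = "briq_volume"
  )
}

#' Score an MRI volume slice by slice
#'
#' Applies [score_slice()] to every slice and aggregates with
#' [aggregate_volume()].
#'
#' @param slices A list of slice matrices, or a 3-D array (sliced along
#'   `axis`).
#' @param cutoff,sequence_tag See [aggregate_volume()].
#' @param axis Slicing axis for a 3-D array input (default 3).
#' @param ... Passed to [score_slice()] (window, weights, ...).
#' @return A `briq_volume` report; see [aggregate_volume()].
#' @examples
#' vol <- phantom_volume(phantom_spec(height = 96, width = 96, seed = 3), 5)
#' rep <- score_volume(vol, sequence_tag = "T2")
#' glance(rep)
#' @export
score_volume <- function(slices, cutoff = NULL,
                         sequence_tag = c("unknown", "T1", "T2"),
                         axis = 3, ...) {
  sequence_tag <- match.arg(sequence_tag)
  if (is.array(slices) && length(dim(slices)) == 3L) {
    slices <- asplit(slices, axis)
    slices <- lapply(slices, function(s) matrix(s, nrow(s), ncol(s)))
  }
  if (!is.list(slices) || length(slices) < 1L) {
    abort("`slices` must be a non-empty list of matrices or a 3-D array.")
  }
  per_slice <- purrr::map_dfr(slices, score_slice, ...)
  aggregate_volume(per_slice, cutoff = cutoff, sequence_tag = sequence_tag)
}

#' @export
print.briq_volume <- function(x, ...) {
  m <- x$means
  cat(sprintf("<briq_volume> %d slices (%s)\n", nrow(x$per_slice), x$sequence_tag))
  cat(sprintf("  mean scores: q1=%.3f q2=%.3f q3=%.3f q4=%.3f Q=%.3f\n",
              m["q1"], m["q2"], m["q3"], m["q4"], m["Q"]))
  cat(sprintf("  cutoff %.2f -> %s\n", x$cutoff,
              if (x$passes) "PASS" else "FAIL"))
  invisible(x)
}

#' Tidy a volume report into per-slice rows
#'
#' @param x A `briq_volume`.
#' @param ... Unused.
#' @return The per-slice tibble (one row per slice).
#' @export
tidy.briq_volume <- function(x, ...) x$per_slice

#' One-row volume summary
#'
#' @param x A `briq_volume`.
#' @param ... Unused.
#' @return Tibble with the mean scores, slice count, cut-off and pass flag.
#' @export
glance.briq_volume <- function(x, ...) {
  m <- as.list(x$means)
  names(m) <- paste0("mean_", names(m))
  tibble(
    n_slices = nrow(x$per_slice), !!!m,
    cutoff = x$cutoff, passes = x$passes, sequence_tag = x$sequence_tag
  )
}

#' Plot per-slice quality profiles for a volume
#'
#' Line plot of the four attribute scores and the total score against slice
#' index, the standard way to eyeball quality variation through a volume.
#'
#' @param object A `briq_volume`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.briq_volume <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_slice,
                              cols = c("q1", "q2", "q3", "q4", "Q"),
                              names_to = "score", values_to = "value")
  long$score <- factor(long$score, levels = c("q1", "q2", "q3", "q4", "Q"),
                       labels = c("luminance contrast (q1)", "texture (q2)",
                                  "texture contrast (q3)", "lightness (q4)",
                                  "total (Q)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$slice, y = .data$value,
                                     colour = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "slice index", y = "quality score", colour = NULL) +
    ggplot2::theme_minimal()
}
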