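#' Perceptual weights for the four quality attributes
#'
#' Weights for luminance contrast (q1), texture (q2), texture contrast (q3)
#' and lightness (q4). The defaults 0.1, 0.1, 0.7, 0.1 reflect that texture
#' contrast contributes roughly ten times more to saliency in natural scenes
#' than luminance contrast. Weights must be non-negative and sum to one.
#'
#' @param w_q1,w_q2,w_q3,w_q4 Non-negative weights summing to 1.
#' @return Named numeric vector of class `briq_weights`.
#' @examples
#' quality_weights()                       # the defaults
#' quality_weights(0.25, 0.25, 0.25, 0.25) # equal weighting
#' @export
quality_weights <- function(w_q1 = 0.1, w_q2 = 0.1, w_q3 = 0.7, w_q4 = 0.1) {
  w <- c(w_q1 = w_q1, w_q2 = w_q2, w_q3 = w_q3, w_q4 = w_q4)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("Weights must be finite and non-negative.")
  }
  if (abs(sum(w) - 1) > 1e-8) {
    abort(sprintf("Weights must sum to 1 (got %.6f).", sum(w)))
  }
  structure(w, class = "briq_weights")
}

check_pair <- function(a, b, kind) {
  ka <- attr(a, "source_kind"); kb <- attr(b, "source_kind")
  if (is.null(ka) || is.null(kb) || ka != kind || kb != kind) {
    abort(sprintf("Both binary images must derive from the %s feature.", kind))
  }
  if (!identical(dim(a), dim(b))) abort("Binary images must have identical dimensions.")
  invisible(NULL)
}

# Shared edge-pixel matching score for q1 / q2.
edge_match_score <- function(a, b, connectivity = 4, edge_denominator = FALSE) {
  na <- attr(a, "n_bright"); nb <- attr(b, "n_bright")
  ea <- edge_pixels(a, connectivity)
  eb <- edge_pixels(b, connectivity)
  num <- sum(ea & eb)
  den <- if (edge_denominator) max(sum(ea), sum(eb)) else max(na, nb)
  if (den == 0L) {
    warn("Both bright sets are empty; returning score 0.")
    return(0)
  }
  num / den
}

#' Luminance contrast quality score (q1)
#'
#' Edge-pixel structural matching of the two grayscale-derived binary images
#' FGMG and FCMG: the number of pixels that are edge pixels of the bright set
#' in both images, divided by the larger of the two bright-pixel counts (the
#' larger count caps the score at 1).
#'
#' @param fgmg,fcmg `briq_binary` images with `source_kind = "grayscale"`.
#' @param connectivity Neighbourhood for edge pixels, 4 or 8.
#' @param edge_denominator If `TRUE`, divide by the larger edge-pixel count
#'   instead of the larger bright count (alternative reading under which an
#'   identical pair scores exactly 1). Default `FALSE`, as printed.
#' @return Score in \[0, 1\]; 0 (with a warning) when both bright sets are
#'   empty.
#' @export
luminance_contrast <- function(fgmg, fcmg, connectivity = 4,
                               edge_denominator = FALSE) {
  check_pair(fgmg, fcmg, "grayscale")
  edge_match_score(fgmg, fcmg, connectivity, edge_denominator)
}

#' Texture quality score (q2)
#'
#' Edge-pixel structural matching of the two contrast-derived binary images
#' FGMC and FCMC, with the same contract as [luminance_contrast()].
#'
#' @param fgmc,fcmc `briq_binary` images with `source_kind = "contrast"`.
#' @inheritParams luminance_contrast
#' @return Score in \[0, 1\].
#' @export
texture <- function(fgmc, fcmc, connectivity = 4, edge_denominator = FALSE) {
  check_pair(fgmc, fcmc, "contrast")
  edge_match_score(fgmc, fcmc, connectivity, edge_denominator)
}

# Pixel-wise agreement (both bright or both dark) over the foreground.
agreement_score <- function(a, b, fg, n_t) {
  if (!identical(dim(a), dim(fg))) abort("Mask dimensions do not match.")
  if (n_t < 1L) abort("`n_t` must be at least 1.")
  agree <- (a == b) & fg
  sum(agree) / n_t
}

#' Texture contrast quality score (q3)
#'
#' Pixel-wise structural matching of FGMC and FCMC: the number of foreground
#' pixels that are bright in both or dark in both, divided by the foreground
#' pixel count n_t. For an ideal undistorted image the two moments coincide,
#' the two binary images are identical, and q3 is exactly 1; for real images
#' q3 reflects the disparity between mu_d and mu_c.
#'
#' @param fgmc,fcmc `briq_binary` images with `source_kind = "contrast"`.
#' @param fg Logical foreground mask.
#' @param n_t Foreground pixel count (defaults to `sum(fg)`).
#' @return Score in \[0, 1\].
#' @export
texture_contrast <- function(fgmc, fcmc, fg, n_t = sum(fg)) {
  check_pair(fgmc, fcmc, "contrast")
  agreement_score(fgmc, fcmc, fg, n_t)
}

#' Lightness quality score (q4)
#'
#' Pixel-wise structural matching of the grayscale-derived pair FGMG and
#' FCMG over the foreground, divided by n_t; the analogue of
#' [texture_contrast()] on the grayscale pair.
#'
#' @param fgmg,fcmg `briq_binary` images with `source_kind = "grayscale"`.
#' @inheritParams texture_contrast
#' @return Score in \[0, 1\].
#' @export
lightness <- function(fgmg, fcmg, fg, n_t = sum(fg)) {
  check_pair(fgmg, fcmg, "grayscale")
  agreement_score(fgmg, fcmg, fg, n_t)
}

#' Total quality score
#'
#' Weighted sum of the four attribute scores, Q = w1 q1 + w2 q2 + w3 q3 +
#' w4 q4, bounded in \[0, 1\] since the weights are convex.
#'
#' @param q1,q2,q3,q4 Attribute scores in \[0, 1\].
#' @param weights A [quality_weights()] vector.
#' @return Total score in \[0, 1\].
#' @export
total_score <- function(q1, q2, q3, q4, weights = quality_weights()) {
  if (!inherits(weights, "briq_weights")) {
    weights <- do.call(quality_weights, as.list(unclass(weights)))
  }
  q <- c(q1, q2, q3, q4)
  if (any(q < -1e-12) || any(q > 1 + 1e-12)) {
    abort("Scores must lie in [0, 1].")
  }
  sum(unclass(weights) * q)
}
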