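# The four binary feature images and their naming:
#   FGMG = grayscale feature thresholded at mu_d (brightness descriptor)
#   FCMG = grayscale feature thresholded at mu_c
#   FCMC = contrast  feature thresholded at mu_c (texture descriptor)
#   FGMC = contrast  feature thresholded at mu_d
# Background pixels are always dark and excluded from every count.

BINARY_NAMES <- c("FGMG", "FCMG", "FCMC", "FGMC")

#' Threshold a feature image at a first moment
#'
#' Global thresholding with the strict inequality `value > moment`: a
#' foreground pixel is bright iff its feature value strictly exceeds the
#' moment. Background pixels are forced dark.
#'
#' @param feat Numeric matrix on \[0, 1\], the feature image.
#' @param fg Logical foreground mask, same dimensions.
#' @param moment Threshold in \[0, 1\] (mu_d or mu_c).
#' @param name One of `"FGMG"`, `"FCMG"`, `"FCMC"`, `"FGMC"`.
#' @return Object of class `briq_binary`: a logical matrix with attributes
#'   `name`, `source_kind` (`"grayscale"` or `"contrast"`),
#'   `threshold_moment` (`"mu_d"` or `"mu_c"`), and `n_bright`.
#' @seealso [binary_features()] for all four images at once.
#' @export
threshold_feature <- function(feat, fg, moment, name = "FGMG") {
  if (!is.matrix(feat) || !is.numeric(feat)) abort("`feat` must be a numeric matrix.")
  check_mask(fg, feat, arg = "fg")
  if (!is.numeric(moment) || length(moment) != 1L || moment < 0 || moment > 1) {
    abort("`moment` must be a single value in [0, 1].")
  }
  name <- match.arg(name, BINARY_NAMES)
  bits <- fg & (feat > moment)
  structure(
    bits,
    class = c("briq_binary", class(bits)),
    name = name,
    source_kind = if (name %in% c("FGMG", "FCMG")) "grayscale" else "contrast",
    threshold_moment = if (name %in% c("FGMG", "FGMC")) "mu_d" else "mu_c",
    n_bright = sum(bits)
  )
}

#' Generate the four binary feature images
#'
#' Applies the four threshold pairings to the grayscale and contrast feature
#' images: grayscale at mu_d (FGMG), grayscale at mu_c (FCMG), contrast at
#' mu_c (FCMC) and contrast at mu_d (FGMC). When the two moments coincide
#' (the ideal-image regime) FGMG equals FCMG and FCMC equals FGMC bitwise.
#'
#' @param gray,contrast Feature images on \[0, 1\], same dimensions.
#' @param fg Logical foreground mask.
#' @param mu_d,mu_c First moments of `gray` and `contrast`; computed with
#'   [first_moment()] over `fg` when omitted.
#' @return Named list with elements `FGMG`, `FCMG`, `FCMC`, `FGMC` (each a
#'   `briq_binary`) plus the moments `mu_d`, `mu_c`.
#' @export
binary_features <- function(gray, contrast, fg,
                            mu_d = first_moment(gray, fg),
                            mu_c = first_moment(contrast, fg)) {
  if (!identical(dim(gray), dim(contrast))) {
    abort("`gray` and `contrast` must have identical dimensions.")
  }
  list(
    FGMG = threshold_feature(gray, fg, mu_d, "FGMG"),
    FCMG = threshold_feature(gray, fg, mu_c, "FCMG"),
    FCMC = threshold_feature(contrast, fg, mu_c, "FCMC"),
    FGMC = threshold_feature(contrast, fg, mu_d, "FGMC"),
    mu_d = mu_d,
    mu_c = mu_c
  )
}

#' Edge pixels of a binary feature image
#'
#' The inner morphological boundary of the bright set: bright pixels having
#' at least one dark (or off-canvas) pixel among their 4-neighbours
#' (8-neighbours with `connectivity = 8`). Edge-pixel structural matching
#' compares only these boundary pixels between two binary images.
#'
#' @param bits Logical matrix (a `briq_binary` or plain mask).
#' @param connectivity 4 (default) or 8.
#' @return Logical matrix, `TRUE` on edge pixels; a subset of the bright set.
#' @export
edge_pixels <- function(bits, connectivity = 4) {
  if (!is.matrix(bits) || !is.logical(bits)) abort("`bits` must be a logical matrix.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  h <- nrow(bits); w <- ncol(bits)
  # off-canvas neighbours count as dark
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1), 2:(w + 1)] <- bits
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  all_bright_nb <- matrix(TRUE, h, w)
  for (o in offs) {
    nb <- padded[(2:(h + 1)) + o[1], (2:(w + 1)) + o[2], drop = FALSE]
    all_bright_nb <- all_bright_nb & nb
  }
  bits & !all_bright_nb
}
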