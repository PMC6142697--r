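#' Extract the foreground (head) mask of an MRI slice
#'
#' Separates the anatomical head region from the near-zero air background.
#' The slice is thresholded with Otsu's method, the largest connected
#' component is retained, interior holes are filled, and a single
#' morphological closing pass smooths the boundary. All image moments and
#' pixel counts downstream are computed against this mask.
#'
#' @param x Numeric matrix of non-negative intensities (the slice).
#' @param fill_holes Fill interior holes of the largest component
#'   (default `TRUE`).
#' @return A logical matrix of the same dimensions, `TRUE` on foreground,
#'   with attribute `n_t` giving the foreground pixel count.
#' @details A constant non-zero slice has no separable background: the full
#'   canvas is returned as foreground (documented degenerate case). An
#'   all-zero slice signals an error ("empty slice").
#' @examples
#' ph <- phantom_generate(phantom_spec(seed = 1))
#' fg <- extract_foreground(ph$slice)
#' sum(fg)
#' @export
extract_foreground <- function(x, fill_holes = TRUE) {
  check_slice(x)
  if (all(x == 0)) {
    abort("empty slice: all intensities are zero, no foreground found.")
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    # constant non-zero image: no background to separate
    mask <- matrix(TRUE, nrow(x), ncol(x))
    attr(mask, "n_t") <- length(mask)
    return(mask)
  }
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  bw <- xn > th
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  comp <- EBImage::imageData(lab) == keep
  comp <- EBImage::Image(comp * 1)
  if (fill_holes) comp <- EBImage::fillHull(comp)
  kern <- EBImage::makeBrush(3, shape = "diamond")
  comp <- EBImage::closing(comp, kern)
  mask <- matrix(as.logical(EBImage::imageData(comp) > 0), nrow(x), ncol(x))
  n_t <- sum(mask)
  if (n_t < 1L) abort("empty slice: no foreground component found.")
  attr(mask, "n_t") <- n_t
  mask
}

#' Min-max rescale a slice to [0, 1]
#'
#' Affine map of the slice intensities so the minimum over the full slice
#' becomes 0 and the maximum 1. The rescaled slice serves as the grayscale
#' feature image; with an air background the zero intensities anchor the
#' lower end. Rank order of pixels is preserved and the map is idempotent on
#' its own output.
#'
#' @param x Numeric matrix of non-negative intensities.
#' @return Numeric matrix on \[0, 1\].
#' @examples
#' rescale_intensity(matrix(c(0, 50, 100, 25), 2, 2))
#' @export
rescale_intensity <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix.")
  rng <- range(x)
  if (!all(is.finite(rng))) abort("`x` contains non-finite values.")
  if (rng[1] == rng[2]) {
    abort("zero dynamic range: slice is constant, cannot rescale.")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Choose the range-filter window for a slice size
#'
#' The local range filter is sensitive to its width: too large loses fine
#' detail, too small loses spatial coherence. The recommended widths are 3, 5
#' and 7 pixels for slices whose larger dimension is comparable to 250, 350
#' and 450 pixels respectively; the nearest size class is chosen.
#'
#' @param height,width Slice dimensions in pixels (each >= 8).
#' @return An odd integer window width: 3, 5 or 7.
#' @examples
#' select_window(256, 256) # 3
#' select_window(350, 350) # 5
#' select_window(448, 408) # 7
#' @export
select_window <- function(height, width) {
  if (height < 8 || width < 8) abort("Slice must be at least 8x8 pixels.")
  size <- max(height, width)
  classes <- c(250, 350, 450)
  widths <- c(3L, 5L, 7L)
  widths[which.min(abs(size - classes))]
}

#' Local contrast feature image (range filter)
#'
#' Sweeps a square window over the rescaled grayscale image and records, at
#' each pixel, the range (max minus min) of the window neighbourhood. For a
#' [0, 1] input the output is again on [0, 1]: near a full-step edge the
#' range is 1, inside a constant region it is 0, so the image captures the
#' local edge density that characterises cortical gray matter. Borders use
#' symmetric (mirror) padding so slice edges do not register spurious
#' contrast.
#'
#' @param gray Numeric matrix on \[0, 1\] (rescaled grayscale feature image).
#' @param window Odd window width (3, 5, 7, ...); see [select_window()].
#' @return Numeric matrix of local ranges, same dimensions as `gray`.
#' @examples
#' g <- matrix(0, 16, 16); g[5:12, 5:12] <- 1
#' c1 <- local_contrast(g, 3)
#' range(c1)
#' @export
local_contrast <- function(gray, window = 3L) {
  if (!is.matrix(gray) || !is.numeric(gray)) abort("`gray` must be a numeric matrix.")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("`window` must be a positive odd integer.")
  if (window > min(dim(gray))) {
    abort("`window` is larger than the image.")
  }
  r <- (window - 1L) %/% 2L
  if (r == 0L) return(gray * 0)
  h <- nrow(gray); w <- ncol(gray)
  xp <- pad_symmetric(gray, r, r)
  hi <- lo <- xp[(r + 1):(r + h), (r + 1):(r + w), drop = FALSE]
  for (di in -r:r) {
    for (dj in -r:r) {
      if (di == 0L && dj == 0L) next
      win <- xp[(r + 1 + di):(r + h + di), (r + 1 + dj):(r + w + dj), drop = FALSE]
      hi <- pmax(hi, win)
      lo <- pmin(lo, win)
    }
  }
  hi - lo
}

#' First moment of a feature image over the foreground
#'
#' The arithmetic mean of the feature values across foreground pixels: mu_d
#' for the grayscale feature image, mu_c for the contrast feature image.
#' These two moments are the global thresholds that define the four binary
#' feature images.
#'
#' @param feat Numeric matrix on \[0, 1\] (a feature image).
#' @param fg Logical foreground mask, same dimensions. Use `NULL` to average
#'   over the full canvas (`moments_over = "full"` behaviour).
#' @return Mean value in \[0, 1\].
#' @export
first_moment <- function(feat, fg = NULL) {
  if (!is.matrix(feat) || !is.numeric(feat)) abort("`feat` must be a numeric matrix.")
  if (is.null(fg)) return(mean(feat))
  check_mask(fg, feat, arg = "fg")
  if (!any(fg)) abort("Foreground mask is empty; first moment undefined.")
  mean(feat[fg])
}
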