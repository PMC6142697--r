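# Two-tissue-class synthetic brain slice: a bright, convoluted cortical-like
# ribbon over a dark interior with smooth blobs, on a zero (air) background,
# finished with a mild Gaussian point-spread function so the slice behaves
# like an acquired image (a blurred version of an ideal two-class image)
# rather than a piecewise-constant drawing.
#
# The ribbon's inner boundary is folded by a broadband angular random field
# (sinusoids spanning ~15-110 cycles with random phases and radial drift,
# squashed through a logistic), giving gyri-like fingers at many scales.
# That folding delivers the high edge density the two-class model assumes of
# cortical gray matter: on a clean phantom the first moment of the contrast
# feature image sits close to the grayscale first moment, which is where
# good-quality clinical slices live (total score around 0.8-0.9).

# internal fold-field constants (see the methods vignette)
FOLD_FREQ_RANGE <- c(15L, 110L)
FOLD_N_HARMONICS <- 40L
FOLD_GAIN <- 3
FOLD_BIAS <- 0.7
FOLD_DRIFT <- 25

#' Specification of a synthetic two-tissue-class brain phantom
#'
#' @param height,width Canvas size in pixels (each >= 32).
#' @param rim_intensity Intensity of the cortical-like folded ribbon.
#' @param interior_intensity Base intensity of the interior tissue. The
#'   T2-like ordering is background < interior < rim; a T1-like phantom
#'   (ribbon darker than interior, both above background) is also accepted.
#' @param background_intensity Air background level, strictly below both
#'   tissue classes (default 0).
#' @param rim_thickness Thickness in pixels of the unfolded base ring from
#'   which the gyral fingers grow (>= 1).
#' @param n_interior_blobs Number of smooth Gaussian blobs added to the
#'   interior (0 for a flat interior).
#' @param wiggle_amplitude Relative amplitude of the low-frequency sinusoidal
#'   perturbation of the head outline (0 for a plain ellipse).
#' @param fold_depth Relative radial depth of the gyri-like folding of the
#'   ribbon's inner boundary, as a fraction of the head radius (0 disables
#'   folding and leaves a smooth annular rim).
#' @param psf_sigma Standard deviation, in pixels, of the Gaussian
#'   point-spread function applied to the rendered tissue classes,
#'   emulating acquisition blur. Set 0 for an exact piecewise-constant
#'   image (e.g. the ideal \{0, 1\} phantom).
#' @param seed Integer seed; the phantom is byte-identical per seed.
#' @return A `phantom_spec` list.
#' @examples
#' phantom_spec(seed = 1)
#' # ideal binary phantom: exact {0,1} values
#' phantom_spec(rim_intensity = 1, interior_intensity = 0,
#'              n_interior_blobs = 0, psf_sigma = 0)
#' @export
phantom_spec <- function(height = 256, width = 256,
                         rim_intensity = 1, interior_intensity = 0.03,
                         background_intensity = 0,
                         rim_thickness = 2, n_interior_blobs = 10,
                         wiggle_amplitude = 0.04, fold_depth = 0.5,
                         psf_sigma = 0.7, seed = 1) {
  if (height < 32 || width < 32) abort("Phantom canvas must be at least 32x32.")
  if (rim_thickness < 1) abort("`rim_thickness` must be >= 1 pixel.")
  ok_ordering <- background_intensity < min(rim_intensity, interior_intensity) ||
    (interior_intensity == background_intensity &&
       rim_intensity > background_intensity)
  if (!ok_ordering) abort("Background must be darker than both tissue classes.")
  if (rim_intensity == interior_intensity) {
    abort("Rim and interior intensities must differ (two tissue classes).")
  }
  if (wiggle_amplitude < 0 || wiggle_amplitude > 0.15) {
    abort("`wiggle_amplitude` must lie in [0, 0.15].")
  }
  if (fold_depth < 0 || fold_depth > 0.6) {
    abort("`fold_depth` must lie in [0, 0.6].")
  }
  if (psf_sigma < 0 || psf_sigma > 3) abort("`psf_sigma` must lie in [0, 3].")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         rim_intensity = rim_intensity,
         interior_intensity = interior_intensity,
         background_intensity = background_intensity,
         rim_thickness = rim_thickness,
         n_interior_blobs = as.integer(n_interior_blobs),
         wiggle_amplitude = wiggle_amplitude,
         fold_depth = fold_depth,
         psf_sigma = psf_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  i <- -r:r
  k <- exp(-outer(i^2, i^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# Render one slice. RNG state is managed by the caller (phantom_generate /
# phantom_volume) so a spec draws the same geometry for every scale.
phantom_render <- function(spec, scale = 1) {
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  margin <- 1 + spec$wiggle_amplitude
  ry <- scale * 0.42 * h / margin
  rx <- scale * 0.42 * w / margin
  if (ry < spec$rim_thickness + 2 || rx < spec$rim_thickness + 2) {
    abort("Phantom geometry does not fit the canvas at this scale.")
  }
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- (row - cy) / ry
  dx <- (col - cx) / rx
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  # low-frequency head-outline wiggle
  ofreq <- sample(5:11, 3)
  ophase <- stats::runif(3, 0, 2 * pi)
  oamp <- spec$wiggle_amplitude * stats::runif(3, 0.5, 1) / 3
  outer_w <- 0
  for (i in 1:3) outer_w <- outer_w + oamp[i] * sin(ofreq[i] * theta + ophase[i])
  outer_b <- 1 + outer_w

  # broadband gyral folding of the inner ribbon boundary
  r_loc <- sqrt((rx * cos(theta))^2 + (ry * sin(theta))^2)
  nk <- FOLD_N_HARMONICS
  ks <- sort(sample(FOLD_FREQ_RANGE[1]:FOLD_FREQ_RANGE[2], nk))
  amps <- rep(1 / sqrt(nk / 2), nk)
  phs <- stats::runif(nk, 0, 2 * pi)
  drift <- stats::runif(nk, -FOLD_DRIFT, FOLD_DRIFT)
  g <- 0
  for (i in seq_len(nk)) {
    g <- g + amps[i] * sin(ks[i] * theta + phs[i] + drift[i] * rho)
  }
  fold <- spec$fold_depth / (1 + exp(-FOLD_GAIN * (g - FOLD_BIAS)))
  inner_b <- outer_b - spec$rim_thickness / r_loc - fold

  head <- rho <= outer_b
  rim <- head & (rho > inner_b)
  interior <- head & !rim

  img <- matrix(spec$background_intensity, h, w)
  img[interior] <- spec$interior_intensity
  img[rim] <- spec$rim_intensity

  if (spec$n_interior_blobs > 0 && any(interior)) {
    span <- spec$rim_intensity - spec$interior_intensity
    bump <- matrix(0, h, w)
    for (b in seq_len(spec$n_interior_blobs)) {
      br <- stats::runif(1, 0, 0.40)
      bt <- stats::runif(1, 0, 2 * pi)
      by <- cy + br * ry * sin(bt)
      bx <- cx + br * rx * cos(bt)
      bs <- stats::runif(1, 0.03, 0.18) * min(rx, ry)
      amp <- stats::runif(1, 0.2, 0.35) * span
      bump <- bump + amp * exp(-((row - by)^2 + (col - bx)^2) / (2 * bs^2))
    }
    cap <- spec$interior_intensity + 0.6 * span
    img[interior] <- pmin(img[interior] + bump[interior], cap)
  }

  if (spec$psf_sigma > 0) {
    img <- conv2_same_symmetric(img, gaussian_kernel(spec$psf_sigma))
    img <- pmax(img, 0)
    img[!head] <- spec$background_intensity  # air stays exactly at background
  }

  labels <- matrix(0L, h, w)
  labels[interior] <- 1L
  labels[rim] <- 2L
  list(slice = img, mask = head, labels = labels, rx = rx, ry = ry)
}

#' Generate a synthetic brain-slice phantom
#'
#' Renders the phantom described by a [phantom_spec()]: an elliptical head on
#' a zero background, a bright cortical-like ribbon whose inner boundary is
#' folded into gyri-like fingers at many angular scales (high edge density),
#' a darker interior with smooth blobs, and a mild Gaussian point-spread
#' function emulating acquisition blur. The ground-truth foreground mask and
#' tissue labels accompany the slice so every pipeline stage can be tested
#' without clinical data.
#'
#' @param spec A [phantom_spec()].
#' @return List with `slice` (numeric matrix), `mask` (logical head mask),
#'   `labels` (integer matrix: 0 background, 1 interior, 2 rim) and `spec`.
#' @examples
#' ph <- phantom_generate(phantom_spec(seed = 42))
#' dim(ph$slice)
#' @export
phantom_generate <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec().")
  out <- with_local_seed(spec$seed, phantom_render(spec))
  list(slice = out$slice, mask = out$mask, labels = out$labels, spec = spec)
}

#' Generate a phantom volume
#'
#' A stack of phantom slices with smoothly varying geometry: the head ellipse
#' is scaled by a spherical-cap profile so the mid-volume slice is largest
#' and the end slices smallest, emulating successive axial slices. The
#' boundary folds are shared across slices (same seed), so geometry varies
#' smoothly through the stack.
#'
#' @param spec A [phantom_spec()] describing the mid-volume slice.
#' @param n_slices Number of slices (>= 1).
#' @return List of `n_slices` slice matrices, with the per-slice ground-truth
#'   masks in attribute `masks` and scale factors in attribute `scales`.
#' @export
phantom_volume <- function(spec = phantom_spec(), n_slices = 14) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec().")
  if (n_slices < 1) abort("`n_slices` must be >= 1.")
  mid <- (n_slices + 1) / 2
  half <- max(mid, n_slices - mid) + 1
  z <- (seq_len(n_slices) - mid) / half
  scales <- sqrt(pmax(1 - z^2, 0.25))
  outs <- lapply(scales, function(s) {
    with_local_seed(spec$seed, phantom_render(spec, scale = s))
  })
  slices <- lapply(outs, `[[`, "slice")
  attr(slices, "masks") <- lapply(outs, `[[`, "mask")
  attr(slices, "scales") <- scales
  slices
}
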