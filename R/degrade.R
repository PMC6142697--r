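# Artificial degradations at levels 1-15, the level scaling the model's
# pixel/percent parameter directly: pillbox radius (circular blur), line
# length (motion blur), percent of max intensity (Rician noise), relative
# amplitude (synthetic bias field).

check_level <- function(level, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else 1
  if (!is.numeric(level) || length(level) != 1L || level < lo || level > 15) {
    abort(sprintf("`level` must be a single value in [%d, 15].", lo))
  }
  level
}

#' Pillbox (circular averaging) kernel
#'
#' Constant inside a disc of the given radius (pixel centres within
#' `radius`), zero outside, normalized to unit sum so interior constant
#' regions and the image mean are preserved.
#'
#' @param radius Disc radius in pixels (>= 1).
#' @return A (2 radius + 1) square matrix summing to 1.
#' @export
pillbox_kernel <- function(radius) {
  radius <- as.integer(radius)
  if (radius < 1L) abort("`radius` must be >= 1.")
  idx <- -radius:radius
  d2 <- outer(idx^2, idx^2, "+")
  k <- (d2 <= radius^2) * 1
  k / sum(k)
}

#' Linear motion-blur kernel
#'
#' A line segment of the given length through the kernel centre at the given
#' angle, rendered with sub-pixel (bilinear) anti-aliasing and normalized to
#' unit sum; approximates the linear motion of a camera over `length`
#' pixels. Anti-aliasing makes the effective blur grow smoothly with length
#' at any angle, instead of jumping as sample points snap to pixels.
#'
#' @param length Line length in pixels (>= 1); length 1 is the identity.
#' @param angle Motion direction in degrees (default 0, horizontal).
#' @return An odd-sized matrix summing to 1.
#' @export
motion_kernel <- function(length, angle = 0) {
  length <- as.integer(length)
  if (length < 1L) abort("`length` must be >= 1.")
  if (length == 1L) return(matrix(1, 1, 1))
  rad <- angle * pi / 180
  half <- (length - 1) / 2
  ts <- seq(-half, half, length.out = 8L * length)
  xs <- ts * cos(rad)
  ys <- ts * sin(rad)
  r <- floor(max(abs(ys))) + 1L
  c <- floor(max(abs(xs))) + 1L
  k <- matrix(0, 2L * r + 1L, 2L * c + 1L)
  for (i in seq_along(ts)) {
    x0 <- floor(xs[i]); y0 <- floor(ys[i])
    fx <- xs[i] - x0;   fy <- ys[i] - y0
    for (dy in 0:1) {
      for (dx in 0:1) {
        wt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
        if (wt > 0) {
          k[r + 1L + y0 + dy, c + 1L + x0 + dx] <-
            k[r + 1L + y0 + dy, c + 1L + x0 + dx] + wt
        }
      }
    }
  }
  # trim empty borders symmetrically, keeping the kernel odd and centred
  while (nrow(k) > 1 && all(k[1, ] == 0) && all(k[nrow(k), ] == 0)) {
    k <- k[2:(nrow(k) - 1), , drop = FALSE]
  }
  while (ncol(k) > 1 && all(k[, 1] == 0) && all(k[, ncol(k)] == 0)) {
    k <- k[, 2:(ncol(k) - 1), drop = FALSE]
  }
  k / sum(k)
}

#' Degrade a slice with circular blur
#'
#' Convolves the slice with a normalized pillbox kernel whose radius in
#' pixels equals the degradation level, using symmetric boundary padding.
#'
#' @param x Slice matrix.
#' @param level Blur level = pillbox radius in pixels, 1-15.
#' @return Blurred slice, same dimensions.
#' @export
degrade_circular_blur <- function(x, level) {
  check_slice(x)
  check_level(level)
  if (level >= min(dim(x)) / 2) {
    abort("Blur radius must be smaller than half the image size.")
  }
  # FFT round-off can leave values a hair below zero; intensities stay >= 0
  pmax(conv2_same_symmetric(x, pillbox_kernel(level)), 0)
}

#' Degrade a slice with linear motion blur
#'
#' Convolves the slice with a normalized line kernel of length `level`
#' pixels at the given angle (symmetric boundary padding). Level 1 is the
#' identity.
#'
#' @param x Slice matrix.
#' @param level Motion length in pixels, 1-15.
#' @param angle Motion direction in degrees (default 0).
#' @return Blurred slice, same dimensions.
#' @export
degrade_motion_blur <- function(x, level, angle = 0) {
  check_slice(x)
  check_level(level)
  k <- motion_kernel(level, angle)
  if (max(dim(k)) >= min(dim(x))) {
    abort("Motion length must be smaller than the image.")
  }
  pmax(conv2_same_symmetric(x, k), 0)
}

#' Degrade a slice with Rician noise
#'
#' The slice is duplicated into real and imaginary channels, independent
#' Gaussian noise of standard deviation sigma = (level / 100) * reference
#' maximum is added to each (signal in the real channel only), and the
#' magnitude is returned: `sqrt((x + g1)^2 + g2^2)`. On a zero image this
#' reduces to Rayleigh noise with mean sigma * sqrt(pi / 2).
#'
#' @param x Slice matrix.
#' @param level Noise level as percent of the reference maximum, 0-15
#'   (0 returns the image unchanged).
#' @param seed Integer seed for reproducibility; unseeded use warns.
#' @param ref_max Reference maximum intensity defining sigma; defaults to
#'   `max(x)`. Supply explicitly for images whose own maximum is not the
#'   intended scale (e.g. a zero image).
#' @return Noisy slice, same dimensions, non-negative.
#' @export
degrade_rician <- function(x, level, seed = NULL, ref_max = max(x)) {
  check_slice(x)
  check_level(level, allow_zero = TRUE)
  sigma <- level / 100 * ref_max
  if (sigma == 0) return(x)
  if (is.null(seed)) {
    warn("`seed` not supplied; Rician noise will not be reproducible.")
    g1 <- rnorm(length(x), 0, sigma)
    g2 <- rnorm(length(x), 0, sigma)
  } else {
    g <- with_local_seed(seed, rnorm(2L * length(x), 0, sigma))
    g1 <- g[seq_along(x)]
    g2 <- g[length(x) + seq_along(x)]
  }
  matrix(sqrt((as.vector(x) + g1)^2 + g2^2), nrow(x), ncol(x))
}

#' Apply a synthetic multiplicative bias field
#'
#' Multiplies the slice by a smooth, strictly positive field — a centred
#' Gaussian bump or a linear ramp — whose amplitude scales with the level
#' (level 15 modulates intensities by +/- 45%). A synthetic stand-in for
#' scanner intensity inhomogeneity used to exercise the metric; it is not a
#' physical coil model.
#'
#' @param x Slice matrix.
#' @param level Amplitude level, 0-15 (0 returns the image unchanged).
#' @param profile `"gaussian"` bump (default) or `"ramp"`.
#' @return Biased slice, same dimensions; attribute `field` carries the
#'   multiplicative field.
#' @export
degrade_bias_field <- function(x, level, profile = c("gaussian", "ramp")) {
  check_slice(x)
  check_level(level, allow_zero = TRUE)
  profile <- match.arg(profile)
  h <- nrow(x); w <- ncol(x)
  amp <- 0.03 * level
  if (level == 0) {
    field <- matrix(1, h, w)
  } else if (profile == "gaussian") {
    row <- matrix(seq_len(h), h, w); col <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    s2 <- (0.45 * max(h, w))^2
    field <- 1 + amp * (exp(-((row - cy)^2 + (col - cx)^2) / (2 * s2)) - 0.5) * 2
  } else {
    ramp <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
    field <- 1 + amp * (ramp - 0.5) * 2
  }
  out <- x * field
  attr(out, "field") <- field
  out
}
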