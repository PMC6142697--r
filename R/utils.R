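# Internal helpers shared across modules.

# Validate a slice: numeric matrix, finite, non-negative, at least 8x8.
check_slice <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(x) < 8L || ncol(x) < 8L) {
    abort(sprintf("`%s` must be at least 8x8 pixels, got %dx%d.",
                  arg, nrow(x), ncol(x)))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (any(x < 0)) {
    abort(sprintf("`%s` contains negative intensities.", arg))
  }
  invisible(x)
}

check_mask <- function(mask, x = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort(sprintf("`%s` must be a logical matrix.", arg))
  }
  if (!is.null(x) && !identical(dim(mask), dim(x))) {
    abort(sprintf("`%s` dimensions %s do not match the image %s.",
                  arg, paste(dim(mask), collapse = "x"),
                  paste(dim(x), collapse = "x")))
  }
  invisible(mask)
}

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Symmetric (edge-mirroring) padding by `a` rows and `b` columns.
pad_symmetric <- function(x, a, b = a) {
  h <- nrow(x); w <- ncol(x)
  if (a >= h || b >= w) {
    abort("Padding exceeds image size; window or kernel too large for image.")
  }
  ri <- c(a:1, 1:h, h:(h - a + 1))
  ci <- c(b:1, 1:w, w:(w - b + 1))
  if (a == 0) ri <- 1:h
  if (b == 0) ci <- 1:w
  x[ri, ci, drop = FALSE]
}
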