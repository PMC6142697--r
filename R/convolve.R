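# FFT-based 2-D convolution with symmetric (reflective) boundary handling.
#
# Blur degradations must preserve the local mean right up to the slice edge;
# mirroring the image into the pad region before the circular FFT convolution
# achieves that without the wrap-around artefacts of a plain FFT filter.

# Full linear convolution of two matrices via zero-padded FFTs.
conv2_full <- function(x, k) {
  n1 <- nrow(x) + nrow(k) - 1L
  n2 <- ncol(x) + ncol(k) - 1L
  xp <- matrix(0, n1, n2)
  kp <- matrix(0, n1, n2)
  xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / (n1 * n2)
}

# "Same"-size convolution with symmetric padding. Kernel dims must be odd.
conv2_same_symmetric <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  if (kh %% 2L == 0L || kw %% 2L == 0L) {
    abort("Convolution kernel must have odd dimensions.")
  }
  a <- (kh - 1L) %/% 2L
  b <- (kw - 1L) %/% 2L
  if (a == 0L && b == 0L) return(x * k[1, 1])
  xp <- pad_symmetric(x, max(a, 1L), max(b, 1L))
  full <- conv2_full(xp, k)
  # centre of the kernel aligned with each original pixel:
  r0 <- max(a, 1L) + a
  c0 <- max(b, 1L) + b
  full[(r0 + 1):(r0 + nrow(x)), (c0 + 1):(c0 + ncol(x)), drop = FALSE]
}
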