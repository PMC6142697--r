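# Independent brute-force reference implementations used to cross-check the
# package. Everything here is written with explicit per-pixel loops and no
# shared code with the package internals.

oracle_rescale <- function(x) {
  lo <- min(x); hi <- max(x)
  (x - lo) / (hi - lo)
}

# local range filter with symmetric (edge-mirroring) padding, by exhaustive
# neighbourhood scan
oracle_local_contrast <- function(x, window) {
  r <- (window - 1) %/% 2
  h <- nrow(x); w <- ncol(x)
  reflect <- function(i, n) {
    # map an out-of-range index onto the mirrored-with-edge-repeat sequence
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- c()
      for (di in -r:r) {
        for (dj in -r:r) {
          vals <- c(vals, x[reflect(i + di, h), reflect(j + dj, w)])
        }
      }
      out[i, j] <- max(vals) - min(vals)
    }
  }
  out
}

oracle_first_moment <- function(feat, fg) {
  tot <- 0; n <- 0L
  for (i in seq_len(nrow(feat))) {
    for (j in seq_len(ncol(feat))) {
      if (fg[i, j]) { tot <- tot + feat[i, j]; n <- n + 1L }
    }
  }
  tot / n
}

oracle_threshold <- function(feat, fg, moment) {
  out <- matrix(FALSE, nrow(feat), ncol(feat))
  for (i in seq_len(nrow(feat))) {
    for (j in seq_len(ncol(feat))) {
      out[i, j] <- fg[i, j] && feat[i, j] > moment
    }
  }
  out
}

oracle_edge_pixels <- function(bits, connectivity = 4) {
  h <- nrow(bits); w <- ncol(bits)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!bits[i, j]) next
      for (o in offs) {
        ii <- i + o[1]; jj <- j + o[2]
        dark <- ii < 1 || ii > h || jj < 1 || jj > w || !bits[ii, jj]
        if (dark) { out[i, j] <- TRUE; break }
      }
    }
  }
  out
}

# edge-pixel matching score (q1/q2 form): co-bright edge pixels over the
# larger bright count
oracle_edge_score <- function(a, b, connectivity = 4) {
  ea <- oracle_edge_pixels(a, connectivity)
  eb <- oracle_edge_pixels(b, connectivity)
  num <- 0L; na <- 0L; nb <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (ea[i, j] && eb[i, j]) num <- num + 1L
      if (a[i, j]) na <- na + 1L
      if (b[i, j]) nb <- nb + 1L
    }
  }
  den <- max(na, nb)
  if (den == 0L) 0 else num / den
}

# pixel-wise agreement score (q3/q4 form)
oracle_agreement_score <- function(a, b, fg) {
  num <- 0L; nt <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (!fg[i, j]) next
      nt <- nt + 1L
      if (a[i, j] == b[i, j]) num <- num + 1L
    }
  }
  num / nt
}

# full slice scoring by the oracle path, sharing only the foreground mask
# and window choice with the caller
oracle_score_slice <- function(x, fg, window, weights = c(0.1, 0.1, 0.7, 0.1)) {
  gray <- oracle_rescale(x)
  con <- oracle_local_contrast(gray, window)
  mu_d <- oracle_first_moment(gray, fg)
  mu_c <- oracle_first_moment(con, fg)
  fgmg <- oracle_threshold(gray, fg, mu_d)
  fcmg <- oracle_threshold(gray, fg, mu_c)
  fcmc <- oracle_threshold(con, fg, mu_c)
  fgmc <- oracle_threshold(con, fg, mu_d)
  q1 <- oracle_edge_score(fgmg, fcmg)
  q2 <- oracle_edge_score(fgmc, fcmc)
  q3 <- oracle_agreement_score(fgmc, fcmc, fg)
  q4 <- oracle_agreement_score(fgmg, fcmg, fg)
  list(mu_d = mu_d, mu_c = mu_c, q1 = q1, q2 = q2, q3 = q3, q4 = q4,
       Q = sum(weights * c(q1, q2, q3, q4)))
}

# direct 2-D convolution ('same', symmetric padding) by explicit summation
oracle_conv2 <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  a <- (nrow(k) - 1) %/% 2; b <- (ncol(k) - 1) %/% 2
  reflect <- function(i, n) if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (u in -a:a) {
        for (v in -b:b) {
          acc <- acc + k[a + 1 + u, b + 1 + v] *
            x[reflect(i - u, h), reflect(j - v, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}
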