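# Single-level 2-D biorthogonal discrete wavelet transform with periodic
# boundary handling, used by wavelet_lowpass(). Implemented here because no
# wavelet package ships with the runtime; perfect reconstruction is covered by
# the test suite.

wavelet_filters <- function(wavelet = c("bior1.3", "haar")) {
  wavelet <- match.arg(wavelet)
  s <- 1 / sqrt(2)
  q <- s / 8  # bior1.3 side taps: 1 / (8 * sqrt(2))
  switch(wavelet,
    "bior1.3" = list(
      dec_lo = c(-q, q, s, s, q, -q),
      dec_hi = c(0, 0, -s, s, 0, 0),
      rec_lo = c(0, 0, s, s, 0, 0),
      rec_hi = c(-q, -q, s, -s, q, q)
    ),
    "haar" = list(
      dec_lo = c(s, s), dec_hi = c(-s, s),
      rec_lo = c(s, s), rec_hi = c(s, -s)
    )
  )
}

# analysis operator (n/2 x n): row i correlates the periodized signal with f
# at shift 2i - offset
dwt_matrix <- function(f, n, offset) {
  m <- n %/% 2L
  A <- matrix(0, m, n)
  for (t in seq_along(f)) {
    cols <- (2L * (seq_len(m) - 1L) + (t - 1L) - offset) %% n + 1L
    A[cbind(seq_len(m), cols)] <- A[cbind(seq_len(m), cols)] + f[t]
  }
  A
}

# synthesis operator (n x n/2): transpose-style scatter of the reversed
# reconstruction filter; with the shared offset this inverts dwt_matrix pairs
idwt_matrix <- function(f, n, offset) {
  m <- n %/% 2L
  S <- matrix(0, n, m)
  fr <- rev(f)
  for (t in seq_along(fr)) {
    rows <- (2L * (seq_len(m) - 1L) + (t - 1L) - offset) %% n + 1L
    S[cbind(rows, seq_len(m))] <- S[cbind(rows, seq_len(m))] + fr[t]
  }
  S
}

dwt2_ops <- function(n, wavelet) {
  f <- wavelet_filters(wavelet)
  off <- as.integer((length(f$dec_lo) - 2L) %/% 2L)
  list(
    Al = dwt_matrix(f$dec_lo, n, off), Ah = dwt_matrix(f$dec_hi, n, off),
    Sl = idwt_matrix(f$rec_lo, n, off), Sh = idwt_matrix(f$rec_hi, n, off)
  )
}

# one-level 2-D DWT of an even-sided matrix; returns subbands LL, LH, HL, HH
dwt2 <- function(x, wavelet = "bior1.3") {
  oh <- dwt2_ops(nrow(x), wavelet)
  ow <- if (ncol(x) == nrow(x)) oh else dwt2_ops(ncol(x), wavelet)
  list(
    LL = oh$Al %*% x %*% t(ow$Al), LH = oh$Al %*% x %*% t(ow$Ah),
    HL = oh$Ah %*% x %*% t(ow$Al), HH = oh$Ah %*% x %*% t(ow$Ah)
  )
}

idwt2 <- function(bands, wavelet = "bior1.3") {
  n <- 2L * nrow(bands$LL)
  m <- 2L * ncol(bands$LL)
  oh <- dwt2_ops(n, wavelet)
  ow <- if (m == n) oh else dwt2_ops(m, wavelet)
  oh$Sl %*% bands$LL %*% t(ow$Sl) + oh$Sl %*% bands$LH %*% t(ow$Sh) +
    oh$Sh %*% bands$HL %*% t(ow$Sl) + oh$Sh %*% bands$HH %*% t(ow$Sh)
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet low-pass denoising
#'
#' One-level 2-D discrete wavelet transform with a biorthogonal wavelet
#' (default `bior1.3`); the three detail subbands are soft-thresholded at the
#' universal threshold `sigma * sqrt(2 * log(N))`, where `sigma` is estimated
#' from the median absolute deviation of the diagonal subband
#' (`median(|HH|) / 0.6745`), and the image is reconstructed and clipped to
#' `[0, 1]`. A constant image passes through unchanged; white noise loses
#' variance.
#'
#' @param img Single-channel image matrix with values in `[0, 1]`.
#' @param wavelet `"bior1.3"` (default) or `"haar"`.
#' @return Denoised image matrix of the same size.
#' @export
wavelet_lowpass <- function(img, wavelet = "bior1.3") {
  if (!is.matrix(img)) stop("`img` must be a single-channel matrix", call. = FALSE)
  f <- wavelet_filters(wavelet)
  if (min(dim(img)) < length(f$dec_lo)) {
    warning("image smaller than the wavelet filter support; returned unchanged")
    return(img)
  }
  h <- nrow(img); w <- ncol(img)
  ph <- h %% 2L; pw <- w %% 2L  # reflect-pad odd sides to even
  x <- img
  if (ph) x <- rbind(x, x[h - 1L, , drop = FALSE])
  if (pw) x <- cbind(x, x[, ncol(x) - 1L, drop = FALSE])
  b <- dwt2(x, wavelet)
  sigma <- median(abs(b$HH)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  if (thr > 0) {
    b$LH <- soft_threshold(b$LH, thr)
    b$HL <- soft_threshold(b$HL, thr)
    b$HH <- soft_threshold(b$HH, thr)
  }
  y <- idwt2(b, wavelet)[seq_len(h), seq_len(w), drop = FALSE]
  pmin(pmax(y, 0), 1)
}
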