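# Framewise acoustic analysis: zero-crossing statistics and MFCC/log-energy
# statistics with regression deltas. Frames are win = frame_len*rate samples,
# advanced by hop = hop_len*rate; frame count = floor((N - win)/hop) + 1.

frame_indices <- function(n, win, hop) {
  if (n < win) stop("signal shorter than one analysis frame")
  n_frames <- (n - win) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  list(n_frames = n_frames, starts = starts)
}

# Pearson moment statistics over frames. Variance is the population second
# moment; skewness m3/m2^1.5 and kurtosis m4/m2^2 (non-excess). A
# zero-variance channel has undefined shape: skew/kurt are NA.
moment_stats <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    return(c(mean = m, variance = 0, skewness = NA_real_, kurtosis = NA_real_))
  }
  c(mean = m, variance = m2,
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2)
}

#' Framewise zero-crossing statistics
#'
#' Counts strict sign changes per analysis frame (zeros are treated as
#' positive, so the count is invariant to amplitude scaling) and summarises
#' the per-frame counts by mean, variance, skewness and kurtosis.
#'
#' @param audio an [audio_signal()].
#' @param frame_len,hop_len frame and hop length in seconds (25 ms / 10 ms).
#' @return named numeric vector `zcr.mean`, `zcr.variance`, `zcr.skewness`,
#'   `zcr.kurtosis`.
#' @export
zcr_stats <- function(audio, frame_len = 0.025, hop_len = 0.010) {
  x <- audio$samples
  win <- round(frame_len * audio$rate)
  hop <- round(hop_len * audio$rate)
  fr <- frame_indices(length(x), win, hop)
  s <- ifelse(x >= 0, 1L, -1L)
  chg <- c(0L, as.integer(s[-1L] != s[-length(s)]))   # chg[i]: sign change at i
  cum <- cumsum(chg)
  # sign changes strictly inside each frame [start, start+win-1]
  counts <- cum[fr$starts + win - 1L] - cum[fr$starts]
  st <- moment_stats(counts)
  names(st) <- paste0("zcr.", names(st))
  st
}

# mel <-> hz (HTK convention)
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, rate, fmin = 0, fmax = rate / 2) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  bin <- floor((nfft + 1) * mel_to_hz(mel_pts) / rate)
  fb <- matrix(0, nrow = n_filters, ncol = nfft %/% 2L + 1L)
  for (j in seq_len(n_filters)) {
    l <- bin[j]; c <- bin[j + 1L]; r <- bin[j + 2L]
    if (c > l) for (k in l:(c - 1L)) fb[j, k + 1L] <- (k - l) / (c - l)
    if (r > c) for (k in c:(r - 1L)) fb[j, k + 1L] <- (r - k) / (r - c)
  }
  fb
}

# orthonormal DCT-II matrix rows 2..(n_out+1) (coefficient 0 dropped)
dct_matrix <- function(n_out, n_in) {
  m <- outer(seq_len(n_out), seq_len(n_in) - 0.5,
             function(i, j) cos(pi * i * j / n_in))
  m * sqrt(2 / n_in)
}

# +/- `width`-frame regression delta with replicated edge padding
delta_regression <- function(mat, width = 2L) {
  n <- ncol(mat)
  denom <- 2 * sum((1:width)^2)
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- matrix(0, nrow = nrow(mat), ncol = n)
  for (w in seq_len(width)) {
    out <- out + w * (mat[, idx(seq_len(n) + w), drop = FALSE] -
                      mat[, idx(seq_len(n) - w), drop = FALSE])
  }
  out / denom
}

#' Framewise MFCC and log-energy statistics
#'
#' Computes 13 mel-frequency cepstral coefficients (c1..c13; 1-based, so the
#' "4th MFCC" is c4) from 26 mel filters on Hamming-windowed 25 ms frames
#' advanced by 10 ms, plus a per-frame log energy channel, then first and
#' second derivatives of every channel by +/-2-frame regression deltas, and
#' finally mean/variance/skewness/kurtosis of each channel across frames.
#' c0 is dropped in favour of the separate log-energy channel.
#'
#' @param audio an [audio_signal()].
#' @param n_mfcc number of cepstral coefficients (default 13).
#' @param n_filters number of mel filters (default 26).
#' @param frame_len,hop_len frame/hop lengths in seconds.
#' @param pre_emphasis pre-emphasis coefficient (default 0.97).
#' @param delta_width half-width of the regression delta window in frames.
#' @return named numeric vector: `mfcc<k>.<stat>`, `mfcc<k>.d1.<stat>`,
#'   `mfcc<k>.d2.<stat>`, `loge.<stat>`, `loge.d1.<stat>`, `loge.d2.<stat>`.
#' @export
mfcc_stats <- function(audio, n_mfcc = 13L, n_filters = 26L,
                       frame_len = 0.025, hop_len = 0.010,
                       pre_emphasis = 0.97, delta_width = 2L) {
  x <- audio$samples
  rate <- audio$rate
  win <- round(frame_len * rate)
  hop <- round(hop_len * rate)
  fr <- frame_indices(length(x), win, hop)
  if (pre_emphasis > 0) x <- c(x[1L], x[-1L] - pre_emphasis * x[-length(x)])
  nfft <- 2^ceiling(log2(win))
  frames <- matrix(0, nrow = win, ncol = fr$n_frames)
  for (i in seq_len(fr$n_frames)) {
    frames[, i] <- x[fr$starts[i]:(fr$starts[i] + win - 1L)]
  }
  eps <- .Machine$double.eps
  loge <- log(pmax(colSums(frames^2), eps))       # frame energy pre-window
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1L) / (win - 1L))
  padded <- rbind(frames * ham, matrix(0, nrow = nfft - win, ncol = fr$n_frames))
  spec <- stats::mvfft(padded)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  pow <- (Mod(spec)^2) / nfft
  fb <- mel_filterbank(n_filters, nfft, rate)
  fbe <- log(pmax(fb %*% pow, eps))                # n_filters x frames
  dct <- dct_matrix(n_mfcc, n_filters)
  cc <- dct %*% fbe                                # n_mfcc x frames
  chan <- rbind(cc, loge)
  rownames(chan) <- c(paste0("mfcc", seq_len(n_mfcc)), "loge")
  d1 <- delta_regression(chan, delta_width)
  d2 <- delta_regression(d1, delta_width)
  c(gather_stats(chan, ""), gather_stats(d1, ".d1"), gather_stats(d2, ".d2"))
}

# stats for each channel (row) of a matrix; names "<channel><suffix>.<stat>"
gather_stats <- function(m, suffix) {
  st <- apply(m, 1L, moment_stats)                 # 4 stats x n channels
  v <- as.vector(st)
  names(v) <- as.vector(outer(rownames(st), colnames(st),
                              function(s, ch) paste0(ch, suffix, ".", s)))
  v
}
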