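#' Simulate a waveform from a timed transcript
#'
#' Produces a noise-burst stand-in for speech: during each token interval
#' (fillers included — a filled pause is audible speech) the signal is
#' smoothed white noise under a raised-cosine onset/offset envelope; between
#' tokens it is exactly zero, so energy-based silence coincides with the
#' annotated gaps to within one hop. This is sufficient to exercise
#' zero-crossing, energy and MFCC code paths; it is not speech, and MFCC
#' values carry no phonetic meaning.
#'
#' @param t a [transcript()] with onset/offset on every token.
#' @param rate sampling rate in Hz (default 16000).
#' @param amplitude burst RMS target (default 0.3).
#' @param seed RNG seed.
#' @return an [audio_signal()] whose duration equals the transcript
#'   duration to within one sample.
#' @export
simulate_waveform <- function(t, rate = 16000, amplitude = 0.3, seed = 1L) {
  tok <- transcript_tokens(t)
  if (!nrow(tok) || anyNA(tok$onset) || anyNA(tok$offset)) {
    stop("waveform simulation needs onset/offset on every token")
  }
  dur <- if (!is.na(t$duration)) t$duration else max(tok$offset) + 0.25
  n <- round(dur * rate)
  x <- numeric(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(nrow(tok))) {
    a <- max(1L, floor(tok$onset[i] * rate) + 1L)
    b <- min(n, ceiling(tok$offset[i] * rate))
    if (b <= a) next
    m <- b - a + 1L
    burst <- stats::rnorm(m)
    # light smoothing (two-point average) tilts energy below Nyquist
    burst <- (burst + c(burst[1L], burst[-m])) / 2
    ramp <- pmin(1, (seq_len(m) - 1L) / (0.01 * rate),
                 (m - seq_len(m)) / (0.01 * rate))
    burst <- burst * pmax(ramp, 0)
    rms <- sqrt(mean(burst^2))
    if (rms > 0) burst <- burst * amplitude / rms
    x[a:b] <- x[a:b] + burst
  }
  audio_signal(pmin(1, pmax(-1, x)), rate)
}
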