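#' Detect pauses from transcript timing
#'
#' Pauses are silent gaps between consecutive non-filler token intervals,
#' computed across utterance boundaries within the sample. A gap of at least
#' `unfilled_min` seconds counts as an unfilled pause; unfilled pauses shorter
#' than `long_min` are "short", the rest "long". A gap that contains a filler
#' token (um/uh) is a filled pause and is excluded from the unfilled counts.
#' The thresholds are not standardised in the clinical literature; the
#' defaults (0.25 s / 1.0 s) are configurable.
#'
#' @param t a [transcript()] whose tokens all carry onset/offset times.
#' @param unfilled_min minimum gap in seconds to count as a pause.
#' @param long_min boundary between short and long pauses, seconds.
#' @return a list of class `pause_set`: `pauses` (data frame `start`, `end`,
#'   `kind`), counts `unfilled`/`short`/`long`, total durations and
#'   `mean_dur` (`NA` when there are no pauses).
#' @export
detect_pauses <- function(t, unfilled_min = 0.25, long_min = 1.0) {
  tok <- transcript_tokens(t)
  if (!nrow(tok)) stop("transcript has no tokens")
  if (anyNA(tok$onset) || anyNA(tok$offset)) {
    stop("pause detection needs onset/offset on every token; ",
         "supply alignment or use simulated timing")
  }
  sp <- tok[!tok$is_filler, , drop = FALSE]
  sp <- sp[order(sp$onset), , drop = FALSE]
  fill <- tok[tok$is_filler, , drop = FALSE]
  out <- data.frame(start = numeric(0), end = numeric(0), kind = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(sp) >= 2L) {
    gs <- sp$offset[-nrow(sp)]
    ge <- sp$onset[-1L]
    len <- ge - gs
    for (i in which(len >= unfilled_min)) {
      # a filler anywhere inside the gap makes it a filled pause
      spanned <- nrow(fill) && any(fill$onset < ge[i] & fill$offset > gs[i])
      if (spanned) next
      out <- rbind(out, data.frame(
        start = gs[i], end = ge[i],
        kind = if (len[i] < long_min) "short" else "long",
        stringsAsFactors = FALSE))
    }
  }
  dur <- out$end - out$start
  structure(list(
    pauses = out,
    unfilled = nrow(out),
    short = sum(out$kind == "short"),
    long = sum(out$kind == "long"),
    total_short_dur = sum(dur[out$kind == "short"]),
    total_long_dur = sum(dur[out$kind == "long"]),
    mean_dur = if (nrow(out)) mean(dur) else NA_real_
  ), class = "pause_set")
}

#' Speech rate and word-duration features
#'
#' Speech rate is non-filler words per minute of elapsed time (declared
#' duration when present, else last offset minus first onset), so pause time
#' counts in the denominator; average word duration is the mean token
#' interval over non-filler words.
#'
#' @param t a [transcript()] with token timing.
#' @return named list: `speech_rate` (words/min), `avg_word_duration` (s),
#'   `total_duration` (s).
#' @export
timing_features <- function(t) {
  tok <- transcript_tokens(t, fillers = FALSE)
  if (!nrow(tok)) stop("transcript has no non-filler tokens")
  if (anyNA(tok$onset) || anyNA(tok$offset)) stop("timing features need token onset/offset")
  dur <- transcript_duration(t)
  if (is.na(dur) || dur <= 0) stop("transcript duration must be positive")
  list(speech_rate = nrow(tok) / dur * 60,
       avg_word_duration = mean(tok$offset - tok$onset),
       total_duration = dur)
}
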