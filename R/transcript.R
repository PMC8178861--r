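#' Construct a token table
#'
#' Tokens are stored as a data frame, one row per token, in utterance order.
#' Times are seconds on a half-open interval `[onset, offset)`; either may be
#' `NA` when no alignment is available.
#'
#' @param surface character vector of surface forms (non-empty strings).
#' @param lemma lemmas; defaults to the lower-cased surface form.
#' @param pos Penn-Treebank part-of-speech tags (`NA` when untagged).
#' @param onset,offset numeric vectors of token times in seconds, or `NA`.
#' @param is_filler logical flag for hesitation markers (um/uh class).
#' @return a `data.frame` with columns `surface`, `lemma`, `pos`, `onset`,
#'   `offset`, `is_filler`.
#' @export
token_table <- function(surface, lemma = tolower(surface), pos = NA_character_,
                        onset = NA_real_, offset = NA_real_,
                        is_filler = FALSE) {
  surface <- as.character(surface)
  if (length(surface) == 0L) {
    return(data.frame(surface = character(), lemma = character(),
                      pos = character(), onset = numeric(), offset = numeric(),
                      is_filler = logical(), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(surface))) stop("token surface forms must be non-empty")
  tok <- data.frame(surface = surface,
                    lemma = as.character(lemma),
                    pos = as.character(pos),
                    onset = as.numeric(onset),
                    offset = as.numeric(offset),
                    is_filler = as.logical(is_filler),
                    stringsAsFactors = FALSE)
  bad <- !is.na(tok$onset) & !is.na(tok$offset) & tok$offset <= tok$onset
  if (any(bad)) {
    stop("token offset must exceed onset (token ", which(bad)[1L], ")")
  }
  tok
}

#' Construct an utterance
#'
#' @param tokens a token table (see [token_table()]).
#' @param speaker speaker id, e.g. `"PAR"`.
#' @param parse optional bracketed constituency parse string.
#' @param start,end optional utterance boundaries in seconds.
#' @return an object of class `speech_utterance`.
#' @export
utterance <- function(tokens, speaker = "PAR", parse = NA_character_,
                      start = NA_real_, end = NA_real_) {
  stopifnot(is.data.frame(tokens))
  u <- list(speaker = as.character(speaker), start = as.numeric(start),
            end = as.numeric(end), parse = as.character(parse),
            tokens = tokens)
  class(u) <- "speech_utterance"
  on <- tokens$onset[!is.na(tokens$onset)]
  if (length(on) > 1L && any(diff(on) < 0)) {
    stop("token onsets within an utterance must be nondecreasing")
  }
  u
}

#' Construct a transcript
#'
#' A transcript is one speech sample: an ordered list of utterances plus
#' sample-level metadata.
#'
#' @param sample_id unique sample identifier.
#' @param utterances list of [utterance()] objects.
#' @param duration total sample duration in seconds (optional; when absent,
#'   consumers fall back to the token time span).
#' @param audio_path optional path to the matching WAV file.
#' @return an object of class `speech_transcript`.
#' @export
transcript <- function(sample_id, utterances = list(), duration = NA_real_,
                       audio_path = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  t <- list(sample_id = sample_id, duration = as.numeric(duration),
            audio_path = as.character(audio_path),
            utterances = utterances)
  class(t) <- "speech_transcript"
  t
}

#' @export
print.speech_transcript <- function(x, ...) {
  n_tok <- sum(vapply(x$utterances, function(u) nrow(u$tokens), integer(1)))
  cat(sprintf("<speech_transcript '%s': %d utterances, %d tokens%s>\n",
              x$sample_id, length(x$utterances), n_tok,
              if (is.na(x$duration)) "" else sprintf(", %.1f s", x$duration)))
  invisible(x)
}

# All tokens of a transcript as one data frame, utterance index attached.
# Fillers are kept; most feature code drops them via `fillers = FALSE`.
transcript_tokens <- function(t, fillers = TRUE) {
  if (length(t$utterances) == 0L) {
    tok <- token_table(character())
    tok$utt <- integer()
    return(tok)
  }
  parts <- lapply(seq_along(t$utterances), function(i) {
    tk <- t$utterances[[i]]$tokens
    if (nrow(tk)) tk$utt <- i else tk$utt <- integer(0)
    tk
  })
  tok <- do.call(rbind, parts)
  rownames(tok) <- NULL
  if (!fillers) tok <- tok[!tok$is_filler, , drop = FALSE]
  tok
}

# Elapsed duration: declared duration if present, else last offset - first onset.
transcript_duration <- function(t) {
  if (!is.na(t$duration)) return(t$duration)
  tok <- transcript_tokens(t)
  on <- tok$onset[!is.na(tok$onset)]
  off <- tok$offset[!is.na(tok$offset)]
  if (!length(on) || !length(off)) return(NA_real_)
  max(off) - min(on)
}
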