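#' Transcript JSON serialisation
#'
#' The on-disk schema is
#' `{"sample_id", "duration", "utterances": [{"speaker", "start", "end",
#' "parse", "tokens": [{"surface", "lemma", "pos", "onset", "offset",
#' "is_filler"}]}]}`. Optional fields are written as `null` and read back as
#' `NA`, so `read_transcript_json(write_transcript_json(t))` reproduces `t`
#' exactly, including millisecond token timing.
#'
#' @param t a [transcript()].
#' @param path file path; for `write_transcript_json`, where to write.
#' @return `read_transcript_json` returns a [transcript()];
#'   `write_transcript_json` returns `path` invisibly.
#' @export
write_transcript_json <- function(t, path) {
  stopifnot(inherits(t, "speech_transcript"))
  doc <- list(
    sample_id = t$sample_id,
    duration = if (is.na(t$duration)) NULL else t$duration,
    audio_path = if (is.na(t$audio_path)) NULL else t$audio_path,
    utterances = lapply(t$utterances, function(u) {
      list(
        speaker = u$speaker,
        start = if (is.na(u$start)) NULL else u$start,
        end = if (is.na(u$end)) NULL else u$end,
        parse = if (is.na(u$parse)) NULL else u$parse,
        tokens = lapply(seq_len(nrow(u$tokens)), function(i) {
          tk <- u$tokens[i, ]
          list(surface = tk$surface,
               lemma = if (is.na(tk$lemma)) NULL else tk$lemma,
               pos = if (is.na(tk$pos)) NULL else tk$pos,
               onset = if (is.na(tk$onset)) NULL else tk$onset,
               offset = if (is.na(tk$offset)) NULL else tk$offset,
               is_filler = tk$is_filler)
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transcript_json
#' @export
read_transcript_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop("transcript JSON is missing required field '", field, "' in ", where)
    }
    x[[field]]
  }
  sid <- need(doc, "sample_id", "document root")
  opt_num <- function(x, field) if (is.null(x[[field]])) NA_real_ else as.numeric(x[[field]])
  opt_chr <- function(x, field) if (is.null(x[[field]])) NA_character_ else as.character(x[[field]])
  utts <- lapply(seq_along(doc$utterances), function(i) {
    u <- doc$utterances[[i]]
    toks <- u$tokens
    if (is.null(toks)) stop("transcript JSON is missing required field 'tokens' in utterance ", i)
    surf <- vapply(toks, function(tk) as.character(need(tk, "surface", paste("utterance", i))), character(1))
    tok <- token_table(
      surface = surf,
      lemma = vapply(toks, opt_chr, character(1), field = "lemma"),
      pos = vapply(toks, opt_chr, character(1), field = "pos"),
      onset = vapply(toks, opt_num, numeric(1), field = "onset"),
      offset = vapply(toks, opt_num, numeric(1), field = "offset"),
      is_filler = vapply(toks, function(tk) isTRUE(tk$is_filler), logical(1)))
    utterance(tok, speaker = opt_chr(u, "speaker"),
              parse = opt_chr(u, "parse"),
              start = opt_num(u, "start"), end = opt_num(u, "end"))
  })
  transcript(as.character(sid), utts,
             duration = opt_num(doc, "duration"),
             audio_path = opt_chr(doc, "audio_path"))
}
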