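#' Read a minimal CHAT (.cha) transcript
#'
#' Supports a deliberately small dialect of the TalkBank CHAT format:
#' `@`-prefixed header lines are skipped, `*TIER:` lines open an utterance,
#' tab-indented continuation lines are joined to the preceding tier, and only
#' the participant tier (default `PAR`) is kept. Bracketed codes
#' (`[//]`, `[: text]`, ...), `&`-prefixed fragments and utterance terminators
#' are stripped; the fillers `&-um` / `&-uh` (and bare `um`/`uh`) are retained
#' with `is_filler = TRUE`. No timing or part-of-speech information is read;
#' annotation is added downstream.
#'
#' @param con a file path or text connection, or a character vector of lines.
#' @param participant tier name treated as the participant (default `"PAR"`).
#' @param sample_id sample id for the resulting transcript.
#' @return a [transcript()].
#' @export
read_chat_transcript <- function(con, participant = "PAR",
                                 sample_id = "chat_sample") {
  lines <- if (is.character(con) && length(con) > 1L) con
           else if (is.character(con) && !file.exists(con) && grepl("\n", con))
             strsplit(con, "\n", fixed = TRUE)[[1L]]
           else readLines(con, warn = FALSE)
  if (length(lines) && !grepl("^@", lines[1L])) {
    warning("CHAT stream does not start with an @ header line")
  }
  # join continuation lines (leading tab) onto the preceding tier line
  joined <- character(0)
  for (ln in lines) {
    if (grepl("^\t", ln) && length(joined)) {
      joined[length(joined)] <- paste(joined[length(joined)], sub("^\t+", "", ln))
    } else {
      joined <- c(joined, ln)
    }
  }
  tier_re <- paste0("^\\*", participant, ":")
  par_lines <- grep(tier_re, joined, value = TRUE)
  if (!length(par_lines)) {
    stop("no participant tiers ('*", participant, ":') found: empty transcript")
  }
  utts <- lapply(par_lines, function(ln) {
    body <- sub(tier_re, "", ln)
    body <- gsub("\x15[^\x15]*\x15", " ", body)   # timing bullets
    body <- gsub("\\[[^]]*\\]", " ", body)              # [codes]
    raw <- strsplit(trimws(body), "\\s+")[[1L]]
    raw <- raw[nzchar(raw)]
    keep <- character(0); filler <- logical(0)
    for (w in raw) {
      if (grepl("^[.!?]$|^\\+", w)) next                       # terminators
      if (grepl("^&-", w)) {                                   # CHAT fillers
        frag <- sub("^&-", "", w)
        if (tolower(frag) %in% c("um", "uh", "er", "eh", "mm", "hm")) {
          keep <- c(keep, frag); filler <- c(filler, TRUE)
        }
        next
      }
      if (grepl("^&", w)) next                                 # fragments
      w2 <- gsub("[,;:\"()<>]", "", w)
      w2 <- sub("[.!?]+$", "", w2)
      if (!nzchar(w2)) next
      keep <- c(keep, w2)
      filler <- c(filler, tolower(w2) %in% c("um", "uh", "er", "eh"))
    }
    if (!length(keep)) return(NULL)
    utterance(token_table(keep, is_filler = filler), speaker = participant)
  })
  utts <- utts[!vapply(utts, is.null, logical(1))]
  if (!length(utts)) stop("participant tiers contained no tokens: empty transcript")
  transcript(sample_id, utts)
}
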