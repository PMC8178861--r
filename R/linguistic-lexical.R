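# Lexical and vocabulary-richness profiles. Fillers are excluded from every
# count; psycholinguistic norm means are taken over covered tokens only, with
# the coverage fraction reported alongside (missing norms never impute 0).

NOUN_TAGS <- c("NN", "NNS", "NNP", "NNPS")
DEMONSTRATIVES <- c("this", "that", "these", "those")
# lexical subordinator list used when no parse information is available
SUBORDINATORS <- c("because", "since", "although", "though", "while", "if",
                   "unless", "until", "when", "whereas", "after", "before")

#' Lexical profile of a transcript
#'
#' Word-level statistics: average word length, word count, mean Zipf
#' frequency, age-of-acquisition / valence / arousal / dominance means over
#' all words and over nouns, and per-100-word usage rates for past-tense
#' verbs, demonstratives, comparative adjectives, plus the ratio of
#' subordinating to coordinating conjunctions.
#'
#' Nouns are tokens tagged NN/NNS/NNP/NNPS; past tense is VBD/VBN;
#' demonstratives are this/that/these/those tagged DT; comparative adjectives
#' are JJR. Subordinators are identified lexically; the
#' subordinate:coordinate ratio is missing when no CC occurs.
#'
#' @param t a [transcript()] with POS tags.
#' @param norms a `norms_table` (see [read_norms_table()]).
#' @return named numeric vector of lexical features, plus norm-coverage
#'   fractions.
#' @export
lexical_stats <- function(t, norms) {
  tok <- transcript_tokens(t, fillers = FALSE)
  nm <- c("avg_word_length", "n_words", "avg_zipf", "avg_aoa_all",
          "avg_aoa_nouns", "avg_valence_all", "avg_valence_nouns",
          "avg_arousal_nouns", "avg_dominance_all", "avg_dominance_nouns",
          "rate_past_tense", "rate_demonstratives", "rate_comparative_adj",
          "ratio_sub_coord", "norm_coverage_all", "norm_coverage_nouns")
  if (!nrow(tok)) {
    out <- rep(NA_real_, length(nm)); names(out) <- nm
    return(out)
  }
  n <- nrow(tok)
  look <- norms_lookup(norms, tok$lemma)
  is_noun <- tok$pos %in% NOUN_TAGS
  cov_mean <- function(v, sel = TRUE) {
    v <- v[sel]; v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  n_cc <- sum(tok$pos == "CC", na.rm = TRUE)
  n_sub <- sum(tolower(tok$surface) %in% SUBORDINATORS &
                 (is.na(tok$pos) | tok$pos %in% c("IN", "WRB")), na.rm = TRUE)
  out <- c(
    avg_word_length = mean(nchar(tok$surface)),
    n_words = as.numeric(n),
    avg_zipf = cov_mean(look$zipf),
    avg_aoa_all = cov_mean(look$aoa),
    avg_aoa_nouns = cov_mean(look$aoa, is_noun),
    avg_valence_all = cov_mean(look$valence),
    avg_valence_nouns = cov_mean(look$valence, is_noun),
    avg_arousal_nouns = cov_mean(look$arousal, is_noun),
    avg_dominance_all = cov_mean(look$dominance),
    avg_dominance_nouns = cov_mean(look$dominance, is_noun),
    rate_past_tense = sum(tok$pos %in% c("VBD", "VBN")) / n * 100,
    rate_demonstratives = sum(tolower(tok$surface) %in% DEMONSTRATIVES &
                                tok$pos %in% "DT", na.rm = TRUE) / n * 100,
    rate_comparative_adj = sum(tok$pos %in% "JJR") / n * 100,
    ratio_sub_coord = if (n_cc > 0) n_sub / n_cc else NA_real_,
    norm_coverage_all = mean(look$covered),
    norm_coverage_nouns = if (any(is_noun)) mean(look$covered[is_noun]) else NA_real_
  )
  out
}

#' Vocabulary richness
#'
#' Type-token ratio on lemmas, moving-average TTR (MATTR) over sliding
#' windows of `window` tokens, Brunet's W = N^(V^-0.165) (lower = richer is
#' reversed: W *decreases* as the vocabulary V grows at fixed N), and
#' Honore's R = 100 log(N) / (1 - V1/V) where V1 is the hapax count
#' (missing when every type is a hapax).
#'
#' @param t a [transcript()].
#' @param window MATTR window size (default 10; MATTR is missing for
#'   shorter transcripts).
#' @return named numeric vector `ttr`, `mattr_w10`, `brunet_w`, `honore_r`.
#' @export
vocabulary_richness <- function(t, window = 10L) {
  tok <- transcript_tokens(t, fillers = FALSE)
  if (!nrow(tok)) stop("transcript has no non-filler tokens")
  lem <- tolower(tok$lemma)
  n <- length(lem)
  v <- length(unique(lem))
  v1 <- sum(table(lem) == 1L)
  mattr <- if (n >= window) {
    mean(vapply(seq_len(n - window + 1L), function(i) {
      length(unique(lem[i:(i + window - 1L)])) / window
    }, numeric(1)))
  } else NA_real_
  c(ttr = v / n,
    mattr_w10 = mattr,
    brunet_w = n^(v^-0.165),
    honore_r = if (v1 == v) NA_real_ else 100 * log(n) / (1 - v1 / v))
}
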