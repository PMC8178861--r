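#' Extract the full named feature vector for one sample
#'
#' Concatenates every feature family under canonical dotted names
#' (`acoustic.pause.*`, `acoustic.rate.*`, `acoustic.zcr.*`,
#' `acoustic.mfcc*.*`, `acoustic.loge.*`, `lexical.*`, `richness.*`,
#' `syntax.*`, `semantic.*`, `graph.*`). The call is deterministic. Inputs
#' that are unavailable (no audio, no norms, ...) make the corresponding
#' features explicitly missing (`NA`), never silently zero.
#'
#' @param t a [transcript()].
#' @param audio optional [audio_signal()]; when `NULL`, waveform spectral
#'   features (ZCR, MFCC, log energy) are `NA`.
#' @param norms optional `norms_table`.
#' @param emb optional `embedding_table`.
#' @param lexicon optional content lexicon.
#' @param pause_unfilled_min,pause_long_min pause thresholds in seconds.
#' @return a named numeric vector covering the whole feature manifest.
#' @export
extract_all <- function(t, audio = NULL, norms = NULL, emb = NULL,
                        lexicon = NULL, pause_unfilled_min = 0.25,
                        pause_long_min = 1.0) {
  manifest <- feature_manifest()
  out <- rep(NA_real_, nrow(manifest))
  names(out) <- manifest$name
  put <- function(out, values, prefix) {
    names(values) <- paste0(prefix, names(values))
    common <- intersect(names(values), names(out))
    out[common] <- values[common]
    out
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)

  tok <- transcript_tokens(t)
  timed <- nrow(tok) > 0 && !anyNA(tok$onset) && !anyNA(tok$offset)
  if (timed) {
    ps <- detect_pauses(t, pause_unfilled_min, pause_long_min)
    out <- put(out, c(unfilled_count = ps$unfilled, short_count = ps$short,
                      long_count = ps$long,
                      total_short_dur = ps$total_short_dur,
                      total_long_dur = ps$total_long_dur,
                      mean_dur = ps$mean_dur), "acoustic.pause.")
    tf <- safe(timing_features(t))
    if (!is.null(tf)) out <- put(out, unlist(tf), "acoustic.rate.")
  }
  if (!is.null(audio)) {
    out <- put(out, zcr_stats(audio), "acoustic.")
    out <- put(out, mfcc_stats(audio), "acoustic.")
  }
  if (!is.null(norms)) {
    out <- put(out, lexical_stats(t, norms), "lexical.")
  } else {
    ls0 <- safe(lexical_stats(t, empty_norms()))
    if (!is.null(ls0)) {
      keep <- c("avg_word_length", "n_words", "rate_past_tense",
                "rate_demonstratives", "rate_comparative_adj", "ratio_sub_coord")
      out <- put(out, ls0[keep], "lexical.")
    }
  }
  rich <- safe(vocabulary_richness(t))
  if (!is.null(rich)) out <- put(out, rich, "richness.")
  syn <- safe(syntactic_rates(t))
  if (!is.null(syn)) out <- put(out, syn, "syntax.")
  out <- put(out, utterance_repetitiveness(t), "semantic.")
  if (!is.null(emb) && !is.null(lexicon)) {
    sim <- safe(picture_similarity(t, emb, lexicon))
    if (!is.null(sim)) out <- put(out, sim, "semantic.")
  }
  gr <- safe(speech_graph_metrics(t))
  if (!is.null(gr)) out <- put(out, gr, "graph.")
  out
}

empty_norms <- function() {
  df <- data.frame(word = character(), zipf = numeric(), aoa = numeric(),
                   valence = numeric(), arousal = numeric(),
                   dominance = numeric(), stringsAsFactors = FALSE)
  class(df) <- c("norms_table", "data.frame")
  df
}

#' The feature manifest
#'
#' Enumerates every feature [extract_all()] can emit: canonical name, family
#' and a one-line definition. [write_feature_manifest()] saves it as TSV.
#'
#' @return a data frame with columns `name`, `family`, `definition`.
#' @export
feature_manifest <- function() {
  rows <- list(
    c("acoustic.pause.unfilled_count", "acoustic", "number of unfilled (silent) pauses >= 0.25 s"),
    c("acoustic.pause.short_count", "acoustic", "number of short pauses (0.25-1.0 s)"),
    c("acoustic.pause.long_count", "acoustic", "number of long pauses (>= 1.0 s)"),
    c("acoustic.pause.total_short_dur", "acoustic", "total duration of short pauses, s"),
    c("acoustic.pause.total_long_dur", "acoustic", "total duration of long pauses, s"),
    c("acoustic.pause.mean_dur", "acoustic", "mean unfilled pause duration, s"),
    c("acoustic.rate.speech_rate", "acoustic", "non-filler words per minute of elapsed time"),
    c("acoustic.rate.avg_word_duration", "acoustic", "mean word duration, s"),
    c("acoustic.rate.total_duration", "acoustic", "sample duration, s"),
    c("lexical.avg_word_length", "lexical", "mean word length in characters"),
    c("lexical.n_words", "lexical", "number of non-filler words"),
    c("lexical.avg_zipf", "lexical", "mean Zipf word frequency over covered words"),
    c("lexical.avg_aoa_all", "lexical", "mean age of acquisition, all covered words"),
    c("lexical.avg_aoa_nouns", "lexical", "mean age of acquisition, nouns"),
    c("lexical.avg_valence_all", "lexical", "mean valence (1-9), all covered words"),
    c("lexical.avg_valence_nouns", "lexical", "mean valence (1-9), nouns"),
    c("lexical.avg_arousal_nouns", "lexical", "mean arousal (1-9), nouns"),
    c("lexical.avg_dominance_all", "lexical", "mean dominance (1-9), all covered words"),
    c("lexical.avg_dominance_nouns", "lexical", "mean dominance (1-9), nouns"),
    c("lexical.rate_past_tense", "lexical", "past-tense verbs (VBD/VBN) per 100 words"),
    c("lexical.rate_demonstratives", "lexical", "demonstrative determiners per 100 words"),
    c("lexical.rate_comparative_adj", "lexical", "comparative adjectives (JJR) per 100 words"),
    c("lexical.ratio_sub_coord", "lexical", "subordinating / coordinating conjunction ratio"),
    c("lexical.norm_coverage_all", "lexical", "fraction of words covered by the norms table"),
    c("lexical.norm_coverage_nouns", "lexical", "fraction of nouns covered by the norms table"),
    c("richness.ttr", "lexical", "type-token ratio on lemmas"),
    c("richness.mattr_w10", "lexical", "moving-average TTR, window 10"),
    c("richness.brunet_w", "lexical", "Brunet's W = N^(V^-0.165)"),
    c("richness.honore_r", "lexical", "Honore's R = 100 log N / (1 - V1/V)"),
    c("syntax.np_dt_nn_rate", "syntactic", "NP -> DT NN productions per 100 words"),
    c("syntax.vp_vbd_np_rate", "syntactic", "VP -> VBD NP productions per 100 words"),
    c("syntax.vp_vbz_pp_rate", "syntactic", "VP with VBZ and PP children per 100 words"),
    c("syntax.vp_sbar_rate", "syntactic", "VP dominating SBAR per 100 words"),
    c("syntax.coord_phrase_rate", "syntactic", "coordinate phrases per 100 words"),
    c("syntax.adjp_rate", "syntactic", "adjective phrases per 100 words"),
    c("syntax.conj_vp_rate", "syntactic", "VP with a CC child per 100 words"),
    c("syntax.coord_per_clause", "syntactic", "coordinate phrases per clause (S/SBAR)"),
    c("semantic.utt_cosdist_mean", "semantic", "mean pairwise utterance cosine distance"),
    c("semantic.utt_cosdist_min", "semantic", "min pairwise utterance cosine distance"),
    c("semantic.utt_cosdist_max", "semantic", "max pairwise utterance cosine distance"),
    c("semantic.pic_max_cosdist", "semantic", "max over utterances of min cosine distance to picture key words"),
    c("semantic.prop_subjects_mentioned", "semantic", "fraction of picture subjects mentioned"),
    c("semantic.prop_subject_words", "semantic", "fraction of tokens that are subject words"),
    c("graph.n_nodes", "graph", "word-adjacency graph: lemma types"),
    c("graph.n_edges", "graph", "word-adjacency graph: transition instances"),
    c("graph.repeated_edges", "graph", "distinct transitions traversed more than once"),
    c("graph.self_loops", "graph", "immediate word repetitions"),
    c("graph.largest_cc", "graph", "largest weakly connected component size"),
    c("graph.density", "graph", "distinct non-loop edges / n(n-1)")
  )
  stats <- c("mean", "variance", "skewness", "kurtosis")
  for (s in stats) {
    rows[[length(rows) + 1L]] <- c(paste0("acoustic.zcr.", s), "acoustic",
                                   paste(s, "of per-frame zero-crossing counts"))
  }
  for (ch in c(paste0("mfcc", 1:13), "loge")) {
    label <- if (ch == "loge") "log energy" else paste0("MFCC c", sub("mfcc", "", ch))
    for (d in c("", ".d1", ".d2")) {
      dl <- c("", " first derivative", " second derivative")[match(d, c("", ".d1", ".d2"))]
      for (s in stats) {
        rows[[length(rows) + 1L]] <- c(paste0("acoustic.", ch, d, ".", s), "acoustic",
                                       paste0(s, " of framewise ", label, dl))
      }
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("name", "family", "definition")
  df
}

#' @rdname feature_manifest
#' @param path output TSV path.
#' @export
write_feature_manifest <- function(path) {
  utils::write.table(feature_manifest(), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Extract a feature matrix for a corpus
#'
#' @param transcripts list of [transcript()] objects.
#' @param audios optional named list of [audio_signal()]s keyed by sample id.
#' @inheritParams extract_all
#' @return a data frame, samples x features, rownames = sample ids.
#' @export
extract_feature_matrix <- function(transcripts, audios = NULL, norms = NULL,
                                   emb = NULL, lexicon = NULL, ...) {
  rows <- lapply(transcripts, function(t) {
    a <- if (!is.null(audios)) audios[[t$sample_id]] else NULL
    extract_all(t, audio = a, norms = norms, emb = emb, lexicon = lexicon, ...)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(transcripts, `[[`, character(1), "sample_id")
  as.data.frame(m)
}
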