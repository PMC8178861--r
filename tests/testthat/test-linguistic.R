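norms <- synthetic_norms()

test_that("lexical statistics match hand arithmetic and report coverage", {
  t <- bag_transcript(c("the", "boy", "runs"))
  t$utterances[[1]]$tokens$pos <- c("DT", "NN", "VBZ")
  ls <- lexical_stats(t, norms)
  expect_equal(unname(ls["avg_word_length"]), 10 / 3)
  expect_equal(unname(ls["n_words"]), 3)
  # "runs" is not in the closed vocabulary: coverage 2/3, means over 2 words
  expect_equal(unname(ls["norm_coverage_all"]), 2 / 3)
  boy <- norms_lookup(norms, "boy"); the <- norms_lookup(norms, "the")
  expect_equal(unname(ls["avg_aoa_all"]), mean(c(boy$aoa, the$aoa)))
  expect_equal(unname(ls["avg_aoa_nouns"]), boy$aoa)
})

test_that("POS-based rates: past tense, demonstratives, comparatives, sub/coord", {
  t <- bag_transcript(c("that", "boy", "fell", "and", "spilled", "because",
                        "taller", "washed"))
  t$utterances[[1]]$tokens$pos <- c("DT", "NN", "VBD", "CC", "VBD", "IN",
                                    "JJR", "VBN")
  ls <- lexical_stats(t, norms)
  expect_equal(unname(ls["rate_past_tense"]), 3 / 8 * 100)     # VBD,VBD,VBN
  expect_equal(unname(ls["rate_demonstratives"]), 1 / 8 * 100)
  expect_equal(unname(ls["rate_comparative_adj"]), 1 / 8 * 100)
  expect_equal(unname(ls["ratio_sub_coord"]), 1)               # because / and
})

test_that("fillers are excluded from lexical counts", {
  t <- bag_transcript(c("boy", "um", "boy"))
  t$utterances[[1]]$tokens$is_filler <- c(FALSE, TRUE, FALSE)
  expect_equal(unname(lexical_stats(t, norms)["n_words"]), 2)
  expect_equal(unname(vocabulary_richness(t)["ttr"]), 0.5)
})

test_that("richness statistics match closed forms", {
  expect_equal(unname(vocabulary_richness(bag_transcript(rep("a", 4)))["ttr"]),
               0.25)
  t10 <- bag_transcript(paste0("w", 1:10))
  r <- vocabulary_richness(t10)
  expect_equal(unname(r["ttr"]), 1)
  expect_equal(unname(r["mattr_w10"]), 1)
  # N = 100, V = 50, V1 = 20 -> Honore = 100 log(100) / (1 - 20/50)
  words <- c(rep(paste0("d", 1:30), each = 2), paste0("p", 1:20),
             rep("q", 20))
  stopifnot(length(words) == 100)
  r2 <- vocabulary_richness(bag_transcript(words))
  expect_equal(unname(r2["honore_r"]), 100 * log(100) / (1 - 20 / 51),
               tolerance = 1e-12)
  expect_equal(unname(r2["brunet_w"]), 100^(51^-0.165))
})

test_that("Honore is missing when every type is a hapax; MATTR needs a window", {
  r <- vocabulary_richness(bag_transcript(c("a", "b", "c")))
  expect_true(is.na(r["honore_r"]))
  expect_true(is.na(r["mattr_w10"]))
})

test_that("Brunet's W decreases as V grows at fixed N", {
  n <- 60
  w <- sapply(c(5, 15, 30, 60), function(v) {
    words <- paste0("t", rep(seq_len(v), length.out = n))
    unname(vocabulary_richness(bag_transcript(words))["brunet_w"])
  })
  expect_true(all(diff(w) < 0))
})

test_that("tree patterns on textbook examples", {
  c1 <- count_tree_patterns("(S (NP (DT the) (NN boy)) (VP (VBZ runs)))")
  expect_equal(unname(c1["np_dt_nn"]), 1L)
  expect_equal(unname(c1["clauses"]), 1L)
  c2 <- count_tree_patterns("(NP (NP (NN cat)) (CC and) (NP (NN dog)))")
  expect_equal(unname(c2["coord_phrase"]), 1L)
  expect_error(count_tree_patterns("(S (NP (DT the)"), "utterance 1")
})

test_that("tree-pattern counts equal the brute-force oracle on random trees", {
  set.seed(202)
  for (i in 1:100) {
    tree <- random_tree()
    got <- count_tree_patterns(render_tree(tree))
    expect_identical(got, oracle_counts(tree))
  }
})

test_that("syntactic rates normalise per 100 words of parsed utterances", {
  tok <- token_table(c("the", "boy", "runs"), pos = c("DT", "NN", "VBZ"))
  t <- transcript("s", list(
    utterance(tok, parse = "(S (NP (DT the) (NN boy)) (VP (VBZ runs)))"),
    utterance(token_table("unparsed"))))
  sr <- syntactic_rates(t)
  expect_equal(unname(sr["np_dt_nn_rate"]), 1 / 3 * 100)
  expect_equal(unname(sr["coord_per_clause"]), 0)
  expect_error(syntactic_rates(bag_transcript(c("a"))), "parse")
})

test_that("utterance cosine distances: identical 0, disjoint 1, hand value", {
  expect_equal(unname(utterance_repetitiveness(
    bag_transcript(c("the", "boy"), c("the", "boy")))["utt_cosdist_mean"]), 0)
  expect_equal(unname(utterance_repetitiveness(
    bag_transcript(c("a", "b"), c("c", "d")))["utt_cosdist_mean"]), 1)
  # u1 = {a:2}, u2 = {a:1, b:1}, u3 = {b:1}
  r <- utterance_repetitiveness(bag_transcript(c("a", "a"), c("a", "b"), "b"))
  d12 <- 1 - 2 / (2 * sqrt(2)); d13 <- 1; d23 <- 1 - 1 / sqrt(2)
  expect_equal(unname(r["utt_cosdist_mean"]), mean(c(d12, d13, d23)))
  expect_equal(unname(r["utt_cosdist_min"]), d12)
  expect_equal(unname(r["utt_cosdist_max"]), 1)
})

test_that("repetitiveness needs two utterances", {
  r <- utterance_repetitiveness(bag_transcript(c("a", "b")))
  expect_true(all(is.na(r)))
})

test_that("picture similarity on orthogonal embeddings gives exact distances", {
  emb <- diag(4)
  rownames(emb) <- c("boy", "girl", "mother", "zebra")
  class(emb) <- c("embedding_table", class(emb))
  lex <- data.frame(word = c("boy", "girl", "mother"),
                    role = "subject", stringsAsFactors = FALSE)
  lex$synonyms <- list(character(0), character(0), character(0))
  # one utterance is exactly a key word -> distance 0; the orthogonal
  # "zebra" utterance has distance exactly 1 to every key word
  t <- bag_transcript("boy", "zebra")
  ps <- picture_similarity(t, emb, lex)
  expect_equal(unname(ps["pic_max_cosdist"]), 1)
  expect_equal(unname(ps["prop_subjects_mentioned"]), 1 / 3)
  expect_equal(unname(ps["prop_subject_words"]), 1 / 2)
  t0 <- bag_transcript("boy")
  expect_equal(unname(picture_similarity(t0, emb, lex)["pic_max_cosdist"]), 0)
})

test_that("synonyms count toward subjects mentioned", {
  emb <- synthetic_embeddings(d = 8)
  lex <- read_content_lexicon()
  t <- bag_transcript(c("the", "lady"))   # synonym of mother
  ps <- picture_similarity(t, emb, lex)
  expect_equal(unname(ps["prop_subjects_mentioned"]), 1 / 3)
})

test_that("speech graph metrics: hand enumeration and degenerate cases", {
  g1 <- speech_graph_metrics(bag_transcript(c("a", "b", "a", "b")))
  expect_equal(unname(g1["n_nodes"]), 2)
  expect_equal(unname(g1["n_edges"]), 3)         # a>b, b>a, a>b
  expect_gte(unname(g1["repeated_edges"]), 1)    # a>b twice
  expect_equal(unname(g1["density"]), 1)         # both ordered pairs seen

  g2 <- speech_graph_metrics(bag_transcript(rep("a", 5)))
  expect_equal(unname(g2["n_nodes"]), 1)
  expect_equal(unname(g2["self_loops"]), 4)

  g3 <- speech_graph_metrics(bag_transcript(c("a", "b"), c("c", "d")))
  expect_lt(unname(g3["largest_cc"]), unname(g3["n_nodes"]))
})

test_that("extract_all emits the full manifest with explicit missingness", {
  cohort <- simulate_cohort(cohort_config(n_per_group = c(HC = 1L, MCI = 0L, AD = 0L)),
                            seed = 5)
  t <- cohort$transcripts[[1]]
  audio <- simulate_waveform(t, rate = 8000, seed = 5)
  fv <- extract_all(t, audio = audio, norms = norms,
                    emb = synthetic_embeddings(), lexicon = read_content_lexicon())
  man <- feature_manifest()
  expect_identical(names(fv), man$name)
  expect_gte(sum(!is.na(fv)), 60)
  expect_false(any(is.nan(fv)))
  # transcript-only call: waveform spectral features are missing, not zero
  fv2 <- extract_all(t, norms = norms)
  expect_true(all(is.na(fv2[grep("^acoustic\\.(zcr|mfcc|loge)", names(fv2))])))
  expect_false(anyNA(fv2[c("acoustic.pause.unfilled_count",
                           "lexical.avg_word_length")]))
  # determinism
  expect_identical(fv, extract_all(t, audio = audio, norms = norms,
                                   emb = synthetic_embeddings(),
                                   lexicon = read_content_lexicon()))
})

test_that("rates are invariant to utterance order", {
  t <- bag_transcript(c("the", "boy"), c("a", "girl", "runs"), c("boy", "falls"))
  for (u in seq_along(t$utterances)) {
    t$utterances[[u]]$tokens$pos <- rep("NN", nrow(t$utterances[[u]]$tokens))
  }
  t_rev <- t; t_rev$utterances <- rev(t$utterances)
  expect_equal(vocabulary_richness(t)["ttr"], vocabulary_richness(t_rev)["ttr"])
  expect_equal(utterance_repetitiveness(t), utterance_repetitiveness(t_rev))
  g <- speech_graph_metrics(t); g_rev <- speech_graph_metrics(t_rev)
  expect_equal(g, g_rev)
})
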