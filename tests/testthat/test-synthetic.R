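test_that("cohort echoes its configuration and is deterministic", {
  cfg <- cohort_config()
  c1 <- simulate_cohort(cfg, seed = 1)
  expect_length(c1$transcripts, 30L)
  expect_equal(as.vector(table(c1$labels$group)), c(10L, 10L, 10L))
  expect_equal(dim(c1$true_severities), c(30L, 4L))
  expect_true(all(c1$true_severities >= 0 & c1$true_severities <= 3))
  c2 <- simulate_cohort(cfg, seed = 1)
  expect_equal(c1$transcripts, c2$transcripts)
  expect_identical(c1$true_severities, c2$true_severities)
  c3 <- simulate_cohort(cfg, seed = 2)
  expect_false(identical(c1$transcripts, c3$transcripts))
})

test_that("non-monotone generator maps are rejected", {
  expect_error(cohort_config(pause_prob_slope = -0.1), "monotone")
})

test_that("severity raises pause counts and lowers speech rate", {
  cfg <- cohort_config()
  sev_hi <- c(word_finding = 3, incoherence = 0, perseveration = 0,
              speech_errors = 0)
  sev_lo <- c(word_finding = 0, incoherence = 0, perseveration = 0,
              speech_errors = 0)
  set.seed(99)
  stats <- sapply(1:20, function(i) {
    hi <- speechmarker:::simulate_transcript("hi", sev_hi, cfg)
    lo <- speechmarker:::simulate_transcript("lo", sev_lo, cfg)
    c(p_hi = detect_pauses(hi)$unfilled, p_lo = detect_pauses(lo)$unfilled,
      r_hi = timing_features(hi)$speech_rate,
      r_lo = timing_features(lo)$speech_rate)
  })
  expect_gt(mean(stats["p_hi", ]), mean(stats["p_lo", ]))
  expect_lt(mean(stats["r_hi", ]), mean(stats["r_lo", ]))
})

test_that("incoherence severity shifts word choice toward later-acquired words", {
  cfg <- cohort_config()
  norms <- synthetic_norms()
  set.seed(17)
  aoa <- sapply(1:15, function(i) {
    hi <- speechmarker:::simulate_transcript("hi",
      c(word_finding = 0, incoherence = 3, perseveration = 0, speech_errors = 0), cfg)
    lo <- speechmarker:::simulate_transcript("lo",
      c(word_finding = 0, incoherence = 0, perseveration = 0, speech_errors = 0), cfg)
    c(hi = unname(lexical_stats(hi, norms)["avg_aoa_all"]),
      lo = unname(lexical_stats(lo, norms)["avg_aoa_all"]))
  })
  expect_gt(mean(aoa["hi", ]), mean(aoa["lo", ]))
})

test_that("perseveration severity increases repetitiveness", {
  cfg <- cohort_config()
  set.seed(18)
  d <- sapply(1:15, function(i) {
    hi <- speechmarker:::simulate_transcript("hi",
      c(word_finding = 0, incoherence = 0, perseveration = 3, speech_errors = 0), cfg)
    lo <- speechmarker:::simulate_transcript("lo",
      c(word_finding = 0, incoherence = 0, perseveration = 0, speech_errors = 0), cfg)
    c(hi = unname(utterance_repetitiveness(hi)["utt_cosdist_mean"]),
      lo = unname(utterance_repetitiveness(lo)["utt_cosdist_mean"]))
  })
  expect_lt(mean(d["hi", ]), mean(d["lo", ]))   # low distance = repetition
})

test_that("waveform is silent in gaps and matches the transcript duration", {
  cfg <- cohort_config()
  cohort <- simulate_cohort(cohort_config(n_per_group = c(HC = 1L, MCI = 0L, AD = 1L)),
                            seed = 21)
  t <- cohort$transcripts[[2]]
  a <- simulate_waveform(t, rate = 8000, seed = 3)
  expect_lte(abs(length(a$samples) - round(t$duration * 8000)), 1)
  ps <- detect_pauses(t)
  expect_gte(ps$unfilled, 1L)
  g <- ps$pauses[which.max(ps$pauses$end - ps$pauses$start), ]
  i0 <- floor(g$start * 8000) + 2L; i1 <- ceiling(g$end * 8000) - 1L
  gap <- a$samples[i0:i1]
  expect_lt(sqrt(mean(gap^2)), 1e-6)
  # and bursts carry energy + zero crossings
  tok <- speechmarker:::transcript_tokens(t)
  w <- tok[1, ]
  burst <- a$samples[(floor(w$onset * 8000) + 10):(ceiling(w$offset * 8000) - 10)]
  expect_gt(sqrt(mean(burst^2)), 0.05)
  expect_gt(mean(sign(burst[-1]) != sign(burst[-length(burst)])), 0.05)
})

test_that("waveform simulation requires timing", {
  expect_error(simulate_waveform(bag_transcript(c("a", "b"))), "onset")
})

test_that("screening a large cohort recovers the built-in feature signs", {
  cfg <- cohort_config(n_per_group = c(HC = 25L, MCI = 25L, AD = 25L))
  cohort <- simulate_cohort(cfg, seed = 31)
  sev <- cohort$true_severities[, "word_finding"]
  feats <- t(sapply(cohort$transcripts, function(t) {
    c(pause = detect_pauses(t)$unfilled,
      rate = timing_features(t)$speech_rate,
      zipf = unname(lexical_stats(t, synthetic_norms())["avg_zipf"]))
  }))
  res <- spearman_screen(as.data.frame(feats), sev)
  expect_true(res[res$feature == "pause", "selected"])
  expect_gt(res[res$feature == "pause", "rho"], 0)
  expect_lt(res[res$feature == "rate", "rho"], 0)
  expect_gt(res[res$feature == "zipf", "rho"], 0)
})
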