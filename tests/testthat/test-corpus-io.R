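test_that("CHAT reader keeps participant tiers, strips codes, flags fillers", {
  lines <- c("@Begin", "@Participants:\tPAR Participant, INV Investigator",
             "*PAR:\tthe boy is on the stool .",
             "*INV:\tokay .",
             "*PAR:\tthe sink [//] the sink is full .",
             "*PAR:\t&-um the water &fr overflowed .")
  t <- read_chat_transcript(lines)
  expect_length(t$utterances, 3L)
  expect_equal(t$utterances[[1]]$tokens$surface,
               c("the", "boy", "is", "on", "the", "stool"))
  # retrace code removed, no terminator tokens
  expect_false(any(grepl("\\[|\\]|\\.", unlist(lapply(t$utterances,
    function(u) u$tokens$surface)))))
  u3 <- t$utterances[[3]]$tokens
  expect_true(u3$is_filler[u3$surface == "um"])
  expect_false("&fr" %in% u3$surface)   # fragment dropped
  # investigator tokens never leak
  expect_false("okay" %in% unlist(lapply(t$utterances, function(u) u$tokens$surface)))
})

test_that("CHAT reader errors on a stream with no participant tier", {
  expect_error(read_chat_transcript(c("@Begin", "*INV:\thello .")),
               "empty transcript")
})

test_that("transcript JSON round-trips losslessly, including timing", {
  tok <- token_table(c("the", "boy", "runs"), pos = c("DT", "NN", "VBZ"),
                     onset = c(0.1, 0.35, 0.801), offset = c(0.3, 0.8, 1.204))
  t <- transcript("s1", list(
    utterance(tok, parse = "(S (NP (DT the) (NN boy)) (VP (VBZ runs)))",
              start = 0.1, end = 1.204),
    utterance(token_table("um", is_filler = TRUE))), duration = 2.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_transcript_json(t, path)
  t2 <- read_transcript_json(path)
  expect_equal(t2, t)
})

test_that("simulated transcripts survive the JSON round trip", {
  cohort <- simulate_cohort(cohort_config(n_per_group = c(HC = 1L, MCI = 1L, AD = 1L)),
                            seed = 11)
  for (t in cohort$transcripts) {
    path <- withr::local_tempfile(fileext = ".json")
    write_transcript_json(t, path)
    expect_equal(read_transcript_json(path), t)
  }
})

test_that("JSON reader names the missing field", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"duration": 3.0, "utterances": []}', path)
  expect_error(read_transcript_json(path), "sample_id")
})

test_that("norms lookup is case-folded and reports absence as NA", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tzipf\taoa\tvalence\tarousal\tdominance",
               "Boy\t5.1\t3.2\t6.5\t4.5\t5.5",
               "jar\t3.8\t\t5.0\t3.5\t4.8"), path)
  norms <- read_norms_table(path)
  hit <- norms_lookup(norms, c("BOY", "jar", "zebra"))
  expect_equal(hit$zipf, c(5.1, 3.8, NA))
  expect_equal(hit$covered, c(TRUE, TRUE, FALSE))
  expect_true(is.na(hit$aoa[2]))          # blank cell stays missing
  expect_false(is.na(hit$valence[2]))
})

test_that("norms reader rejects a missing header and dedupes last-wins", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tzipf", "boy\t5"), bad)
  expect_error(read_norms_table(bad), "header")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tzipf\taoa\tvalence\tarousal\tdominance",
               "boy\t1\t1\t1\t1\t1", "boy\t2\t2\t2\t2\t2"), dup)
  expect_warning(norms <- read_norms_table(dup), "last row wins")
  expect_equal(norms_lookup(norms, "boy")$zipf, 2)
})

test_that("embedding reader infers d and rejects inconsistent lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("boy 1 0 0 0", "girl 0 1 0 0", "jar 0 0 1 0"), path)
  emb <- read_embeddings(path)
  expect_equal(dim(emb), c(3L, 4L))
  writeLines(c("boy 1 0 0 0", "girl 0 1 0"), path)
  expect_error(read_embeddings(path), "dimension")
  writeLines(c("boy 1 0 x 0"), path)
  expect_error(read_embeddings(path), "line 1")
  writeLines(c("boy 0 0 0 0"), path)
  expect_error(read_embeddings(path), "zero")
})

test_that("synthetic embeddings round-trip through the text format", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_synthetic_embeddings(path, d = 8, seed = 7)
  emb <- read_embeddings(path)
  ref <- synthetic_embeddings(d = 8, seed = 7)
  expect_equal(rownames(emb), rownames(ref))
  expect_equal(unclass(emb), unclass(ref), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("WAV I/O round-trips PCM audio and downmixes is not needed for mono", {
  sr <- 16000
  silence <- audio_signal(rep(0, sr), sr)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(silence, path)
  back <- read_wav(path)
  expect_equal(length(back$samples), sr)
  expect_equal(back$rate, sr)
  expect_true(all(back$samples == 0))
  tone <- audio_signal(0.5 * sin(2 * pi * 440 * (0:999) / sr), sr)
  write_wav(tone, path)
  expect_equal(read_wav(path)$samples, tone$samples, tolerance = 1e-4)
})

test_that("rating CSV validates the 0..3 range and names the offending cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,characteristic,rater_id,rating",
               "s1,word_finding,r1,2", "s1,word_finding,r2,5"), path)
  expect_error(read_ratings_csv(path), "s1.*r2|r2.*s1")
  writeLines(c("sample_id,characteristic,rater_id,rating",
               "s1,word_finding,r1,2", "s1,word_finding,r2,3"), path)
  panel <- read_ratings_csv(path)
  expect_s3_class(panel, "rating_panel")
  expect_equal(nrow(panel), 2L)
})

test_that("readers are deterministic", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_synthetic_norms(path)
  expect_identical(read_norms_table(path), read_norms_table(path))
})
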