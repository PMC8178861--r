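test_that("gaps below threshold are not pauses; short/long partition is exact", {
  t0 <- timed_transcript(c("a", "b"), onsets = c(0, 0.5), durs = 0.4)
  expect_equal(detect_pauses(t0)$unfilled, 0L)   # gap 0.1 < 0.25

  # gaps of 0.3 (short) and 1.5 (long)
  t1 <- timed_transcript(c("a", "b", "c"), onsets = c(0, 0.7, 2.6),
                         durs = c(0.4, 0.4, 0.4))
  ps <- detect_pauses(t1)
  expect_equal(ps$unfilled, 2L)
  expect_equal(ps$short, 1L)
  expect_equal(ps$long, 1L)
  expect_equal(ps$mean_dur, 0.9)
  expect_equal(ps$total_short_dur + ps$total_long_dur,
               sum(ps$pauses$end - ps$pauses$start))
  expect_equal(ps$short + ps$long, ps$unfilled)
})

test_that("a gap spanned by a filler token is a filled pause, not unfilled", {
  t <- timed_transcript(c("a", "um", "b"), onsets = c(0, 0.45, 1.0),
                        durs = c(0.4, 0.3, 0.4),
                        fillers = c(FALSE, TRUE, FALSE))
  expect_equal(detect_pauses(t)$unfilled, 0L)    # 0.6 s gap but filled
})

test_that("pause detection demands timing", {
  t <- bag_transcript(c("a", "b"))
  expect_error(detect_pauses(t), "timing")
})

test_that("speech rate and word duration match hand arithmetic", {
  on <- seq(0, by = 2 / 3, length.out = 30)
  t <- timed_transcript(paste0("w", 1:30), onsets = on, durs = 0.3)
  t$duration <- 20
  tf <- timing_features(t)
  expect_equal(tf$speech_rate, 90)               # 30 words / 20 s * 60
  t2 <- timed_transcript(c("a", "b"), onsets = c(0, 1), durs = c(0.2, 0.4))
  expect_equal(timing_features(t2)$avg_word_duration, 0.3)
})

test_that("frame counting matches the closed form on random shapes", {
  set.seed(31)
  for (i in 1:20) {
    win <- sample(50:400, 1); hop <- sample(20:200, 1)
    n <- win + sample(0:5000, 1)
    fr <- speechmarker:::frame_indices(n, win, hop)
    expect_equal(fr$n_frames, floor((n - win) / hop) + 1)
    expect_lte(fr$starts[fr$n_frames] + win - 1L, n)
  }
  expect_error(speechmarker:::frame_indices(10, 100, 10), "shorter")
})

test_that("ZCR: constant signal counts zero, sine matches 2f*frame analytics", {
  const <- audio_signal(rep(0.5, 16000), 16000)
  st <- zcr_stats(const)
  expect_equal(unname(st["zcr.mean"]), 0)
  expect_equal(unname(st["zcr.variance"]), 0)

  sine <- audio_signal(sin(2 * pi * 100 * (0:15999) / 16000), 16000)
  m <- unname(zcr_stats(sine)["zcr.mean"])
  expect_lt(abs(m - 2 * 100 * 0.025), 1)         # ~5 sign changes per frame
})

test_that("ZCR statistics are invariant to amplitude scaling", {
  set.seed(7)
  x <- rnorm(8000)
  a1 <- zcr_stats(audio_signal(x, 8000))
  a2 <- zcr_stats(audio_signal(10 * x, 8000))
  expect_equal(a1, a2)
})

test_that("MFCC statistics match the frozen independent reference", {
  audio <- reference_noise_audio()
  st <- mfcc_stats(audio)
  ref <- read.csv(test_path("mfcc_reference.csv"), stringsAsFactors = FALSE)
  expect_true(all(ref$name %in% names(st)))
  expect_equal(unname(st[ref$name]), ref$value, tolerance = 1e-6)
  expect_lt(max(abs(st[ref$name] - ref$value)), 1e-6)
})

test_that("delta of a constant channel is zero; energy scaling shifts log energy", {
  # without pre-emphasis every frame of an alternating signal is identical,
  # so every channel is constant and its regression delta is exactly zero
  const <- audio_signal(rep(c(0.4, -0.4), 4000), 8000)
  st <- mfcc_stats(const, pre_emphasis = 0)
  expect_equal(unname(st["mfcc1.d1.mean"]), 0, tolerance = 1e-10)
  expect_equal(unname(st["loge.d2.mean"]), 0, tolerance = 1e-10)

  set.seed(9)
  x <- rnorm(8000)
  s1 <- mfcc_stats(audio_signal(x, 8000))
  s2 <- mfcc_stats(audio_signal(2 * x, 8000))
  # doubling amplitude quadruples power: log-energy mean shifts by log 4
  expect_equal(unname(s2["loge.mean"] - s1["loge.mean"]), log(4),
               tolerance = 1e-8)
  expect_equal(unname(s2["loge.d1.mean"]), unname(s1["loge.d1.mean"]),
               tolerance = 1e-8)
  expect_lt(abs(s1["loge.d1.mean"]), 0.05)
})

test_that("audio shorter than one frame is an error", {
  expect_error(mfcc_stats(audio_signal(rnorm(10), 8000)), "frame")
  expect_error(zcr_stats(audio_signal(rnorm(10), 8000)), "frame")
})
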