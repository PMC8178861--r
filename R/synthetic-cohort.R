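# Synthetic cohort generator. Emulates a three-group (HC/MCI/AD) study of
# ~1-minute Cookie-Theft-style picture descriptions: each sample carries a
# latent severity in [0, 3] per clinical speech characteristic, and every
# generator map is monotone in that severity, so downstream screening must
# recover the built-in signs (more pauses, slower speech, more frequent
# words with word-finding difficulty; higher AoA and lower valence with
# incoherence; more repetition and a smaller vocabulary with perseveration;
# more subordinate-clause fragments with speech errors).

CHARACTERISTICS <- c("word_finding", "incoherence", "perseveration",
                     "speech_errors")

#' Synthetic cohort configuration
#'
#' Defaults define the study conditions: 10 samples per group (30 total),
#' 5 raters with rating noise SD 0.35, group severity distributions per
#' characteristic on the latent 0-3 scale, and monotone severity-to-
#' generator slopes.
#'
#' @param n_per_group samples per group, named `HC`, `MCI`, `AD`.
#' @param severity_means,severity_sds 3 x 4 matrices (group x
#'   characteristic) of latent severity means/SDs; severities are clipped
#'   to `[0, 3]`.
#' @param n_raters,rater_sd,rater_bias_sd rating-panel parameters.
#' @param pause_prob_base,pause_prob_slope probability a between-word gap is
#'   an unfilled pause: `base + slope * s` (word-finding severity).
#' @param pause_meanlog_base,pause_meanlog_slope lognormal meanlog of pause
#'   duration.
#' @param word_dur_meanlog_base,word_dur_meanlog_slope lognormal meanlog of
#'   word duration.
#' @param filler_prob_base,filler_prob_slope probability of a filled pause.
#' @param zipf_slope,aoa_slope,valence_slope word-sampling weight slopes.
#' @param repetition_base,repetition_slope utterance-repetition probability
#'   (perseveration severity).
#' @param vocab_base,vocab_slope content vocabulary size `round(base -
#'   slope * s)` (perseveration severity).
#' @param subordinate_base,subordinate_slope subordinate/fragment template
#'   weight (speech-errors severity).
#' @param n_utterances_range inclusive range of utterances per sample.
#' @param sample_rate waveform sampling rate, Hz.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(HC = 10L, MCI = 10L, AD = 10L),
                          severity_means = NULL, severity_sds = NULL,
                          n_raters = 5L, rater_sd = 0.35, rater_bias_sd = 0,
                          pause_prob_base = 0.06, pause_prob_slope = 0.09,
                          pause_meanlog_base = log(0.40),
                          pause_meanlog_slope = 0.25,
                          word_dur_meanlog_base = log(0.22),
                          word_dur_meanlog_slope = 0.06,
                          filler_prob_base = 0.02, filler_prob_slope = 0.03,
                          zipf_slope = 0.5, aoa_slope = 0.35,
                          valence_slope = 0.3,
                          repetition_base = 0.05, repetition_slope = 0.10,
                          vocab_base = 19, vocab_slope = 3,
                          subordinate_base = 0.05, subordinate_slope = 0.15,
                          n_utterances_range = c(12L, 18L),
                          sample_rate = 16000) {
  if (is.null(severity_means)) {
    severity_means <- rbind(
      HC  = c(word_finding = 0.3, incoherence = 0.3, perseveration = 0.2,
              speech_errors = 0.2),
      MCI = c(1.5, 1.3, 0.6, 0.6),
      AD  = c(2.3, 2.0, 1.4, 1.2))
    colnames(severity_means) <- CHARACTERISTICS
  }
  if (is.null(severity_sds)) {
    severity_sds <- rbind(HC = c(0.3, 0.3, 0.25, 0.25),
                          MCI = c(0.5, 0.5, 0.4, 0.4),
                          AD = c(0.5, 0.5, 0.5, 0.5))
    colnames(severity_sds) <- CHARACTERISTICS
  }
  slopes <- c(pause_prob_slope, pause_meanlog_slope, word_dur_meanlog_slope,
              filler_prob_slope, zipf_slope, aoa_slope, valence_slope,
              repetition_slope, vocab_slope, subordinate_slope)
  if (any(slopes < 0)) {
    stop("severity-to-generator slopes must be non-negative (monotone maps)")
  }
  if (rater_sd < 0) stop("rater_sd must be non-negative")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

clip03 <- function(x) pmin(3, pmax(0, x))

# weighted sampling of one word row from the vocab subset with a given tag
pick_word <- function(vocab, tag, w) {
  cand <- which(vocab$pos == tag)
  if (!length(cand)) stop("no vocabulary entry with tag ", tag)
  p <- w[cand]
  cand[sample.int(length(cand), 1L, prob = p / sum(p))]
}

# utterance templates: each returns surface/pos vectors and a parse with the
# sampled words substituted
utterance_templates <- function() {
  list(
    progressive = function(pick) {
      n1 <- pick("NN"); vg <- pick("VBG")
      list(surface = c("the", n1$word, "is", vg$word),
           pos = c("DT", "NN", "VBZ", "VBG"),
           lemma = c("the", n1$lemma, "be", vg$lemma),
           parse = sprintf("(S (NP (DT the) (NN %s)) (VP (VBZ is) (VP (VBG %s))))",
                           n1$word, vg$word))
    },
    locative = function(pick) {
      n1 <- pick("NN"); n2 <- pick("NN")
      list(surface = c("the", n1$word, "stands", "on", "the", n2$word),
           pos = c("DT", "NN", "VBZ", "IN", "DT", "NN"),
           lemma = c("the", n1$lemma, "stand", "on", "the", n2$lemma),
           parse = sprintf(
             "(S (NP (DT the) (NN %s)) (VP (VBZ stands) (PP (IN on) (NP (DT the) (NN %s)))))",
             n1$word, n2$word))
    },
    past = function(pick) {
      n1 <- pick("NN"); vd <- pick("VBD"); n2 <- pick("NN")
      list(surface = c("the", n1$word, vd$word, "the", n2$word),
           pos = c("DT", "NN", "VBD", "DT", "NN"),
           lemma = c("the", n1$lemma, vd$lemma, "the", n2$lemma),
           parse = sprintf("(S (NP (DT the) (NN %s)) (VP (VBD %s) (NP (DT the) (NN %s))))",
                           n1$word, vd$word, n2$word))
    },
    coordination = function(pick) {
      n1 <- pick("NN"); n2 <- pick("NN"); vg <- pick("VBG")
      list(surface = c("the", n1$word, "and", "the", n2$word, "are", vg$word),
           pos = c("DT", "NN", "CC", "DT", "NN", "VBP", "VBG"),
           lemma = c("the", n1$lemma, "and", "the", n2$lemma, "be", vg$lemma),
           parse = sprintf(
             "(S (NP (NP (DT the) (NN %s)) (CC and) (NP (DT the) (NN %s))) (VP (VBP are) (VP (VBG %s))))",
             n1$word, n2$word, vg$word))
    },
    subordinate = function(pick) {
      n1 <- pick("NN"); j <- pick("JJ"); vz <- pick("VBZ")
      list(surface = c("the", n1$word, "is", j$word, "because", "it", vz$word),
           pos = c("DT", "NN", "VBZ", "JJ", "IN", "PRP", "VBZ"),
           lemma = c("the", n1$lemma, "be", j$lemma, "because", "it", vz$lemma),
           parse = sprintf(
             "(S (NP (DT the) (NN %s)) (VP (VBZ is) (ADJP (JJ %s)) (SBAR (IN because) (S (NP (PRP it)) (VP (VBZ %s))))))",
             n1$word, j$word, vz$word))
    },
    demonstrative = function(pick) {
      n1 <- pick("NN"); j <- pick("JJ")
      list(surface = c("that", n1$word, "is", j$word),
           pos = c("DT", "NN", "VBZ", "JJ"),
           lemma = c("that", n1$lemma, "be", j$lemma),
           parse = sprintf("(S (NP (DT that) (NN %s)) (VP (VBZ is) (ADJP (JJ %s))))",
                           n1$word, j$word))
    },
    pronoun = function(pick) {
      vz <- pick("VBZ"); n1 <- pick("NN")
      list(surface = c("she", vz$word, "the", n1$word),
           pos = c("PRP", "VBZ", "DT", "NN"),
           lemma = c("she", vz$lemma, "the", n1$lemma),
           parse = sprintf("(S (NP (PRP she)) (VP (VBZ %s) (NP (DT the) (NN %s))))",
                           vz$word, n1$word))
    },
    comparative = function(pick) {
      n1 <- pick("NN"); n2 <- pick("NN")
      list(surface = c("the", n1$word, "is", "taller", "than", "the", n2$word),
           pos = c("DT", "NN", "VBZ", "JJR", "IN", "DT", "NN"),
           lemma = c("the", n1$lemma, "be", "tall", "than", "the", n2$lemma),
           parse = sprintf(
             "(S (NP (DT the) (NN %s)) (VP (VBZ is) (ADJP (JJR taller) (PP (IN than) (NP (DT the) (NN %s))))))",
             n1$word, n2$word))
    }
  )
}

# generate one transcript given the per-characteristic severity vector
simulate_transcript <- function(sample_id, sev, cfg) {
  vocab <- synthetic_vocab()
  s_wf <- sev[["word_finding"]]; s_inc <- sev[["incoherence"]]
  s_per <- sev[["perseveration"]]; s_err <- sev[["speech_errors"]]
  # perseveration shrinks the usable content vocabulary (nouns)
  nouns <- which(vocab$pos %in% c("NN", "NNS"))
  keep_n <- max(6L, round(cfg$vocab_base - cfg$vocab_slope * s_per))
  noun_order <- nouns[order(-vocab$zipf[nouns])]
  drop_nouns <- setdiff(noun_order, noun_order[seq_len(min(keep_n, length(noun_order)))])
  # word-sampling weights: frequent words with word-finding severity, late-
  # acquired and low-valence words with incoherence
  w <- exp(cfg$zipf_slope * s_wf * (vocab$zipf - 4) / 2 +
             cfg$aoa_slope * s_inc * (vocab$aoa - 5) / 3 -
             cfg$valence_slope * s_inc * (vocab$valence - 5) / 3)
  w[drop_nouns] <- 1e-9
  pick <- function(tag) vocab[pick_word(vocab, tag, w), , drop = FALSE]

  templates <- utterance_templates()
  tnames <- names(templates)
  tw <- stats::setNames(rep(1, length(tnames)), tnames)
  tw["subordinate"] <- (cfg$subordinate_base + cfg$subordinate_slope * s_err) /
    cfg$subordinate_base
  tw["coordination"] <- exp(-0.4 * s_wf)
  tw["past"] <- exp(0.25 * (s_wf + s_inc) / 2)

  n_utt <- sample(seq(cfg$n_utterances_range[1], cfg$n_utterances_range[2]), 1L)
  rep_prob <- min(0.9, cfg$repetition_base + cfg$repetition_slope * s_per)
  utt_specs <- list()
  for (i in seq_len(n_utt)) {
    if (i > 1L && stats::runif(1) < rep_prob) {
      utt_specs[[i]] <- utt_specs[[sample.int(i - 1L, 1L)]]
    } else {
      tmpl <- templates[[sample(tnames, 1L, prob = tw / sum(tw))]]
      utt_specs[[i]] <- tmpl(pick)
    }
  }

  # timing: word durations lognormal in word-finding severity; between-word
  # gaps are short articulation gaps, unfilled pauses, or filler-bridged gaps
  p_pause <- min(0.85, cfg$pause_prob_base + cfg$pause_prob_slope * s_wf)
  p_fill <- min(0.5, cfg$filler_prob_base + cfg$filler_prob_slope * s_wf)
  t_now <- 0.5
  utts <- list()
  for (i in seq_along(utt_specs)) {
    sp <- utt_specs[[i]]
    n_tok <- length(sp$surface)
    surface <- sp$surface; posv <- sp$pos; lemv <- sp$lemma
    onset <- numeric(0); offset <- numeric(0); fill <- logical(0)
    surf_out <- character(0); pos_out <- character(0); lem_out <- character(0)
    for (j in seq_len(n_tok)) {
      u <- stats::runif(1)
      if (j > 1L || i > 1L) {
        if (u < p_pause) {
          t_now <- t_now + stats::rlnorm(1, cfg$pause_meanlog_base +
                                           cfg$pause_meanlog_slope * s_wf, 0.45)
        } else if (u < p_pause + p_fill) {
          # filled pause: gap bridged by a filler token
          gap <- stats::rlnorm(1, cfg$pause_meanlog_base +
                                 cfg$pause_meanlog_slope * s_wf, 0.45)
          f_dur <- min(0.35, gap * 0.6)
          f_on <- t_now + (gap - f_dur) / 2
          surf_out <- c(surf_out, sample(c("um", "uh"), 1L))
          pos_out <- c(pos_out, "UH"); lem_out <- c(lem_out, surf_out[length(surf_out)])
          onset <- c(onset, f_on); offset <- c(offset, f_on + f_dur)
          fill <- c(fill, TRUE)
          t_now <- t_now + gap
        } else {
          t_now <- t_now + stats::runif(1, 0.02, 0.12)
        }
      }
      dur <- stats::rlnorm(1, cfg$word_dur_meanlog_base +
                             cfg$word_dur_meanlog_slope * s_wf, 0.18)
      surf_out <- c(surf_out, surface[j]); pos_out <- c(pos_out, posv[j])
      lem_out <- c(lem_out, lemv[j])
      onset <- c(onset, t_now); offset <- c(offset, t_now + dur)
      fill <- c(fill, FALSE)
      t_now <- t_now + dur
    }
    tok <- token_table(surf_out, lemma = lem_out, pos = pos_out,
                       onset = onset, offset = offset, is_filler = fill)
    tok <- tok[order(tok$onset), , drop = FALSE]
    rownames(tok) <- NULL
    utts[[i]] <- utterance(tok, parse = sp$parse,
                           start = min(tok$onset), end = max(tok$offset))
  }
  transcript(sample_id, utts, duration = t_now + 0.5)
}

#' Simulate a three-group cohort of picture descriptions
#'
#' Draws a latent severity per characteristic for each sample from its
#' group's severity distribution, then generates a severity-linked
#' transcript (timed, POS-tagged, with template parses). Deterministic given
#' `(cfg, seed)`.
#'
#' @param cfg a [cohort_config()].
#' @param seed RNG seed.
#' @return list: `transcripts` (named list), `labels` (data frame
#'   `sample_id`, `group`), `true_severities` (samples x characteristics
#'   matrix), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1L) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  ids <- sprintf("%s%02d", tolower(groups), stats::ave(seq_along(groups),
                                                       groups, FUN = seq_along))
  sev <- matrix(NA_real_, nrow = length(ids), ncol = length(CHARACTERISTICS),
                dimnames = list(ids, CHARACTERISTICS))
  for (i in seq_along(ids)) {
    g <- groups[i]
    sev[i, ] <- clip03(stats::rnorm(length(CHARACTERISTICS),
                                    mean = cfg$severity_means[g, ],
                                    sd = cfg$severity_sds[g, ]))
  }
  transcripts <- lapply(seq_along(ids), function(i) {
    simulate_transcript(ids[i], sev[i, ], cfg)
  })
  names(transcripts) <- ids
  list(transcripts = transcripts,
       labels = data.frame(sample_id = ids,
                           group = factor(groups, levels = c("HC", "MCI", "AD")),
                           stringsAsFactors = FALSE),
       true_severities = sev,
       config = cfg)
}

#' Simulate a clinician rating panel from latent severities
#'
#' Each rater's rating is `clip(round(severity + bias_r + N(0, rater_sd)),
#' 0, 3)`; `bias_r ~ N(0, rater_bias_sd)` is an optional rater-specific
#' shift shared across items.
#'
#' @param true_severities samples x characteristics matrix (or a numeric
#'   vector for a single characteristic).
#' @param n_raters number of raters.
#' @param rater_sd rating noise SD (>= 0).
#' @param seed RNG seed.
#' @param rater_bias_sd SD of the per-rater bias (default 0).
#' @return a `rating_panel` long data frame.
#' @export
simulate_rating_panel <- function(true_severities, n_raters = 5L,
                                  rater_sd = 0.35, seed = 1L,
                                  rater_bias_sd = 0) {
  if (rater_sd < 0) stop("rater_sd must be non-negative")
  if (is.null(dim(true_severities))) {
    true_severities <- matrix(true_severities,
                              ncol = 1L,
                              dimnames = list(names(true_severities), "rating"))
  }
  stopifnot(all(true_severities >= 0 & true_severities <= 3))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bias <- stats::rnorm(n_raters, 0, rater_bias_sd)
  rows <- list()
  for (r in seq_len(n_raters)) {
    noise <- matrix(stats::rnorm(length(true_severities), 0, rater_sd),
                    nrow = nrow(true_severities))
    rat <- clip03(round(true_severities + bias[r] + noise))
    rows[[r]] <- data.frame(
      sample_id = rep(rownames(true_severities), ncol(true_severities)),
      characteristic = rep(colnames(true_severities),
                           each = nrow(true_severities)),
      rater_id = sprintf("rater%02d", r),
      rating = as.integer(as.vector(rat)),
      stringsAsFactors = FALSE)
  }
  rating_panel(do.call(rbind, rows))
}

#' Simulate data from a common-factor model
#'
#' Draws `X = F Lambda' + E` with factor scores `F ~ N(0, Phi)` and
#' independent normal uniquenesses, then standardises the columns. The
#' implied correlation matrix `Lambda Phi Lambda' + Psi` must be positive
#' semi-definite.
#'
#' @param lambda p x k loading matrix.
#' @param phi k x k factor correlation matrix (default identity).
#' @param uniquenesses length-p vector (default `1 - diag(Lambda Phi
#'   Lambda')`).
#' @param n number of rows to draw.
#' @param seed RNG seed.
#' @return an n x p matrix with standardised columns.
#' @export
simulate_factor_model <- function(lambda, phi = diag(ncol(lambda)), n,
                                  uniquenesses = NULL, seed = 1L) {
  lambda <- as.matrix(lambda)
  k <- ncol(lambda); p <- nrow(lambda)
  common <- lambda %*% phi %*% t(lambda)
  if (is.null(uniquenesses)) uniquenesses <- 1 - diag(common)
  if (any(uniquenesses < 0)) stop("negative uniqueness: loadings too large")
  sigma <- common + diag(uniquenesses, p)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("implied correlation matrix is not positive semi-definite")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cph <- chol(phi)
  f <- matrix(stats::rnorm(n * k), nrow = n) %*% cph
  e <- matrix(stats::rnorm(n * p), nrow = n) %*% diag(sqrt(uniquenesses), p)
  x <- f %*% t(lambda) + e
  scale(x)
}
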