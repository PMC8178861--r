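# Shared fixtures: hand-built transcripts and an independent random-tree
# generator with its own brute-force pattern counter (used as an oracle for
# the package's tree matching).

# transcript with explicit timing: words is a character vector, onsets and
# durations numeric vectors (recycled); one utterance unless split is given
timed_transcript <- function(words, onsets, durs = 0.3, pos = "NN",
                             fillers = rep(FALSE, length(words)),
                             sample_id = "fx", split = NULL) {
  durs <- rep_len(durs, length(words))
  pos <- rep_len(pos, length(words))
  groups <- if (is.null(split)) rep(1L, length(words)) else split
  utts <- lapply(unique(groups), function(g) {
    i <- which(groups == g)
    utterance(token_table(words[i], pos = pos[i], onset = onsets[i],
                          offset = onsets[i] + durs[i], is_filler = fillers[i]))
  })
  transcript(sample_id, utts)
}

# plain untimed transcript from utterance word lists
bag_transcript <- function(..., sample_id = "fx") {
  utts <- lapply(list(...), function(w) utterance(token_table(w)))
  transcript(sample_id, utts)
}

# ---- independent random toy-parse oracle ------------------------------------

PRETERMS <- c("DT", "NN", "VBD", "VBZ", "VBG", "CC", "IN", "JJ", "PRP")
PHRASES <- c("S", "NP", "VP", "PP", "SBAR", "ADJP")

random_tree <- function(depth = 0L) {
  if (depth >= 3L || (depth > 0L && runif(1) < 0.45)) {
    lab <- sample(PRETERMS, 1L)
    return(list(label = lab, word = paste0("w", sample.int(20, 1L)),
                children = list()))
  }
  lab <- if (depth == 0L) "S" else sample(PHRASES, 1L)
  n_kids <- sample(1:3, 1L)
  list(label = lab, word = NULL,
       children = lapply(seq_len(n_kids), function(i) random_tree(depth + 1L)))
}

render_tree <- function(node) {
  if (!is.null(node$word)) {
    sprintf("(%s %s)", node$label, node$word)
  } else {
    sprintf("(%s %s)", node$label,
            paste(vapply(node$children, render_tree, character(1)),
                  collapse = " "))
  }
}

# exhaustive pattern counts on the helper's own tree structure
oracle_counts <- function(tree) {
  counts <- c(np_dt_nn = 0L, vp_vbd_np = 0L, vp_vbz_pp = 0L, vp_sbar = 0L,
              coord_phrase = 0L, adjp = 0L, conj_vp = 0L, clauses = 0L,
              n_leaves = 0L)
  walk <- function(node) {
    if (!is.null(node$word)) {
      counts["n_leaves"] <<- counts["n_leaves"] + 1L
      return(invisible())
    }
    kids <- vapply(node$children, `[[`, character(1), "label")
    if (node$label == "NP" && length(kids) == 2L && kids[1] == "DT" &&
          kids[2] == "NN") counts["np_dt_nn"] <<- counts["np_dt_nn"] + 1L
    if (node$label == "VP" && length(kids) == 2L && kids[1] == "VBD" &&
          kids[2] == "NP") counts["vp_vbd_np"] <<- counts["vp_vbd_np"] + 1L
    if (node$label == "VP" && any(kids == "VBZ") && any(kids == "PP"))
      counts["vp_vbz_pp"] <<- counts["vp_vbz_pp"] + 1L
    if (node$label == "VP" && subtree_has_label(node, "SBAR"))
      counts["vp_sbar"] <<- counts["vp_sbar"] + 1L
    flanked <- FALSE
    for (pos in seq_along(kids)) {
      if (kids[pos] == "CC" && pos > 1L && pos < length(kids) &&
            kids[pos - 1L] == kids[pos + 1L]) flanked <- TRUE
    }
    if (flanked) counts["coord_phrase"] <<- counts["coord_phrase"] + 1L
    if (node$label == "ADJP") counts["adjp"] <<- counts["adjp"] + 1L
    if (node$label == "VP" && any(kids == "CC"))
      counts["conj_vp"] <<- counts["conj_vp"] + 1L
    if (node$label %in% c("S", "SBAR"))
      counts["clauses"] <<- counts["clauses"] + 1L
    for (ch in node$children) walk(ch)
  }
  subtree_has_label <- function(node, lab) {
    for (ch in node$children) {
      if (ch$label == lab || subtree_has_label(ch, lab)) return(TRUE)
    }
    FALSE
  }
  walk(tree)
  counts
}

# the 20 seeded panels whose pingouin reference values are frozen in
# icc_reference.csv
reference_icc_panel <- function(i) {
  set.seed(5000 + i)
  sev <- runif(30, 0, 3)
  pmax(pmin(round(sev + matrix(rnorm(150, 0, 0.5), 30, 5)), 3), 0)
}

# the seeded noise fixture whose NumPy-reference MFCC statistics are frozen
# in mfcc_reference.csv
reference_noise_audio <- function() {
  set.seed(48151623)
  audio_signal(rnorm(4800), 8000)
}
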