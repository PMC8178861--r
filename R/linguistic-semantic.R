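# Semantic profile: utterance repetitiveness (bag-of-lemma cosine distances),
# similarity of the description to picture content via word embeddings, and
# word-adjacency graph topology.

# bag-of-lemmas count vectors for each utterance (fillers excluded)
utterance_bags <- function(t) {
  bags <- lapply(t$utterances, function(u) {
    lem <- tolower(u$tokens$lemma[!u$tokens$is_filler])
    if (!length(lem)) return(NULL)
    table(lem)
  })
  bags[!vapply(bags, is.null, logical(1))]
}

cosine_distance <- function(a, b) {
  words <- union(names(a), names(b))
  va <- as.numeric(a[words]); va[is.na(va)] <- 0
  vb <- as.numeric(b[words]); vb[is.na(vb)] <- 0
  1 - sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Utterance repetitiveness via pairwise cosine distance
#'
#' Each utterance is a bag-of-lemmas count vector; the cosine distance
#' 1 - cos is computed over all unordered utterance pairs. Low mean distance
#' means the same words recur across utterances (increased repetition);
#' disjoint vocabularies give distance 1.
#'
#' @param t a [transcript()] with at least 2 utterances containing
#'   non-filler tokens (otherwise all fields are `NA`).
#' @return named numeric vector `utt_cosdist_mean`, `utt_cosdist_min`,
#'   `utt_cosdist_max`.
#' @export
utterance_repetitiveness <- function(t) {
  bags <- utterance_bags(t)
  if (length(bags) < 2L) {
    return(c(utt_cosdist_mean = NA_real_, utt_cosdist_min = NA_real_,
             utt_cosdist_max = NA_real_))
  }
  pairs <- utils::combn(length(bags), 2L)
  d <- apply(pairs, 2L, function(ij) cosine_distance(bags[[ij[1L]]], bags[[ij[2L]]]))
  c(utt_cosdist_mean = mean(d), utt_cosdist_min = min(d), utt_cosdist_max = max(d))
}

#' Similarity of the description to picture content
#'
#' Each utterance is represented as the mean embedding of its covered lemmas.
#' Per utterance, the distance to the picture is the minimum cosine distance
#' over the content key words; `pic_max_cosdist` is the maximum of those
#' per-utterance distances — high values flag utterances far from any
#' picture content. Also reports the fraction of subject key words mentioned
#' (a synonym from the lexicon counts) and the fraction of tokens that are
#' subject words.
#'
#' @param t a [transcript()].
#' @param emb an `embedding_table` (see [read_embeddings()]).
#' @param lexicon content lexicon data frame (see [read_content_lexicon()]).
#' @return named numeric vector `pic_max_cosdist`,
#'   `prop_subjects_mentioned`, `prop_subject_words`.
#' @export
picture_similarity <- function(t, emb, lexicon) {
  tok <- transcript_tokens(t, fillers = FALSE)
  lemmas_by_utt <- lapply(t$utterances, function(u) {
    tolower(u$tokens$lemma[!u$tokens$is_filler])
  })
  keys <- lexicon$word[lexicon$word %in% rownames(emb)]
  if (!length(keys)) stop("no content key word has an embedding")
  key_mat <- emb[keys, , drop = FALSE]
  key_norm <- sqrt(rowSums(key_mat^2))
  utt_dist <- vapply(lemmas_by_utt, function(lem) {
    lem <- lem[lem %in% rownames(emb)]
    if (!length(lem)) return(NA_real_)
    v <- colMeans(emb[lem, , drop = FALSE])
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NA_real_)
    min(1 - as.numeric(key_mat %*% v) / (key_norm * nv))
  }, numeric(1))
  pic_max <- if (all(is.na(utt_dist))) NA_real_ else max(utt_dist, na.rm = TRUE)
  subj <- lexicon[lexicon$role == "subject", , drop = FALSE]
  lem_all <- tolower(tok$lemma)
  subj_hit <- vapply(seq_len(nrow(subj)), function(i) {
    any(lem_all %in% c(subj$word[i], subj$synonyms[[i]]))
  }, logical(1))
  subj_words <- unique(c(subj$word, unlist(subj$synonyms)))
  c(pic_max_cosdist = pic_max,
    prop_subjects_mentioned = if (nrow(subj)) mean(subj_hit) else NA_real_,
    prop_subject_words = if (nrow(tok)) sum(lem_all %in% subj_words) / nrow(tok)
                         else NA_real_)
}

#' Word-adjacency speech graph metrics
#'
#' Builds a directed multigraph whose nodes are lemma types and whose edges
#' are consecutive non-filler token pairs within utterances, then reports
#' node/edge counts, repeated edges (distinct ordered pairs traversed more
#' than once), self-loop edge instances, the largest weakly connected
#' component, and density (distinct non-loop edges over n(n-1); `NA` for a
#' single-node graph).
#'
#' @param t a [transcript()] with at least 2 non-filler tokens.
#' @return named numeric vector `n_nodes`, `n_edges`, `repeated_edges`,
#'   `self_loops`, `largest_cc`, `density`.
#' @export
speech_graph_metrics <- function(t) {
  seqs <- lapply(t$utterances, function(u) tolower(u$tokens$lemma[!u$tokens$is_filler]))
  total <- sum(lengths(seqs))
  if (total < 2L) stop("speech graph needs at least 2 non-filler tokens")
  from <- character(0); to <- character(0)
  for (s in seqs) {
    if (length(s) >= 2L) {
      from <- c(from, s[-length(s)])
      to <- c(to, s[-1L])
    }
  }
  nodes <- unique(unlist(seqs))
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                                stringsAsFactors = FALSE),
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  pair <- paste(from, to, sep = "\r")
  multiplicity <- table(pair)
  n <- length(nodes)
  distinct_nonloop <- sum(vapply(strsplit(names(multiplicity), "\r", fixed = TRUE),
                                 function(p) p[1L] != p[2L], logical(1)))
  comp <- igraph::components(g, mode = "weak")
  c(n_nodes = n,
    n_edges = length(from),
    repeated_edges = sum(multiplicity >= 2L),
    self_loops = sum(from == to),
    largest_cc = max(comp$csize),
    density = if (n >= 2L) distinct_nonloop / (n * (n - 1)) else NA_real_)
}
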