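# Constituency-parse pattern counts. Parses are Penn-Treebank style bracketed
# strings, e.g. "(S (NP (DT the) (NN boy)) (VP (VBZ runs)))".

#' Parse a bracketed constituency string
#'
#' @param s a bracketed parse string.
#' @return a nested list tree: `list(label, children)`; leaves have a
#'   `word` field instead of children.
#' @export
parse_bracketed <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1L]]
  pos <- 1L
  parse_node <- function() {
    if (pos > length(toks) || toks[pos] != "(") stop("expected '(' in parse string")
    pos <<- pos + 1L
    if (pos > length(toks) || toks[pos] %in% c("(", ")")) stop("missing node label in parse string")
    label <- toks[pos]; pos <<- pos + 1L
    children <- list(); word <- NULL
    while (pos <= length(toks) && toks[pos] != ")") {
      if (toks[pos] == "(") {
        children[[length(children) + 1L]] <- parse_node()
      } else {
        word <- toks[pos]; pos <<- pos + 1L
      }
    }
    if (pos > length(toks)) stop("unbalanced brackets in parse string")
    pos <<- pos + 1L   # consume ')'
    if (is.null(word)) list(label = label, children = children)
    else list(label = label, word = word, children = list())
  }
  node <- parse_node()
  if (pos <= length(toks)) stop("trailing content after parse tree")
  node
}

tree_nodes <- function(node) {
  c(list(node), unlist(lapply(node$children, tree_nodes), recursive = FALSE))
}

tree_leaf_count <- function(node) {
  if (!length(node$children)) return(if (is.null(node$word)) 0L else 1L)
  sum(vapply(node$children, tree_leaf_count, integer(1)))
}

dominates <- function(node, label) {
  any(vapply(tree_nodes(node)[-1L], function(n) n$label == label, logical(1)))
}

#' Count syntactic patterns in a set of parse trees
#'
#' Patterns counted (on every internal node of every tree):
#' * `np_dt_nn`: NP whose children are exactly `DT NN`;
#' * `vp_vbd_np`: VP whose children are exactly `VBD NP` (past-tense verb
#'   phrase with a noun phrase);
#' * `vp_vbz_pp`: VP with a VBZ child and a PP child (3rd-person singular
#'   present verb phrase with a prepositional phrase);
#' * `vp_sbar`: VP dominating an SBAR anywhere below it (verb phrase with a
#'   subordinate clause);
#' * `coord_phrase`: any node with a CC child flanked by same-category
#'   sibling constituents;
#' * `adjp`: ADJP nodes;
#' * `conj_vp`: VP with a CC child;
#' * `clauses`: S or SBAR nodes.
#'
#' @param parses character vector of bracketed parse strings.
#' @return named integer vector of pattern counts plus `n_leaves`.
#' @export
count_tree_patterns <- function(parses) {
  counts <- c(np_dt_nn = 0L, vp_vbd_np = 0L, vp_vbz_pp = 0L, vp_sbar = 0L,
              coord_phrase = 0L, adjp = 0L, conj_vp = 0L, clauses = 0L,
              n_leaves = 0L)
  for (i in seq_along(parses)) {
    tree <- tryCatch(parse_bracketed(parses[i]),
                     error = function(e) stop("utterance ", i, ": ", conditionMessage(e)))
    counts["n_leaves"] <- counts["n_leaves"] + tree_leaf_count(tree)
    for (node in tree_nodes(tree)) {
      if (!length(node$children)) next
      kid_labels <- vapply(node$children, `[[`, character(1), "label")
      if (node$label == "NP" && identical(kid_labels, c("DT", "NN"))) {
        counts["np_dt_nn"] <- counts["np_dt_nn"] + 1L
      }
      if (node$label == "VP" && identical(kid_labels, c("VBD", "NP"))) {
        counts["vp_vbd_np"] <- counts["vp_vbd_np"] + 1L
      }
      if (node$label == "VP" && "VBZ" %in% kid_labels && "PP" %in% kid_labels) {
        counts["vp_vbz_pp"] <- counts["vp_vbz_pp"] + 1L
      }
      if (node$label == "VP" && dominates(node, "SBAR")) {
        counts["vp_sbar"] <- counts["vp_sbar"] + 1L
      }
      cc <- which(kid_labels == "CC")
      if (any(cc > 1L & cc < length(kid_labels) &
                kid_labels[pmax(cc - 1L, 1L)] ==
                  kid_labels[pmin(cc + 1L, length(kid_labels))])) {
        counts["coord_phrase"] <- counts["coord_phrase"] + 1L
      }
      if (node$label == "ADJP") counts["adjp"] <- counts["adjp"] + 1L
      if (node$label == "VP" && "CC" %in% kid_labels) {
        counts["conj_vp"] <- counts["conj_vp"] + 1L
      }
      if (node$label %in% c("S", "SBAR")) counts["clauses"] <- counts["clauses"] + 1L
    }
  }
  counts
}

#' Syntactic production rates
#'
#' Counts the patterns of [count_tree_patterns()] over the parsed utterances
#' of a transcript and normalises to rates per 100 words (non-filler tokens
#' of parsed utterances only), plus coordinate phrases per clause.
#'
#' @param t a [transcript()] with bracketed parses on at least one utterance.
#' @return named numeric vector: `*_rate` per-100-word rates for each
#'   pattern, and `coord_per_clause`.
#' @export
syntactic_rates <- function(t) {
  has_parse <- vapply(t$utterances, function(u) !is.na(u$parse), logical(1))
  if (!any(has_parse)) stop("no utterance carries a bracketed parse")
  parses <- vapply(t$utterances[has_parse], `[[`, character(1), "parse")
  counts <- count_tree_patterns(parses)
  n_words <- sum(vapply(t$utterances[has_parse], function(u) {
    sum(!u$tokens$is_filler)
  }, numeric(1)))
  if (n_words == 0) n_words <- counts[["n_leaves"]]
  per100 <- function(k) as.numeric(counts[[k]]) / n_words * 100
  c(np_dt_nn_rate = per100("np_dt_nn"),
    vp_vbd_np_rate = per100("vp_vbd_np"),
    vp_vbz_pp_rate = per100("vp_vbz_pp"),
    vp_sbar_rate = per100("vp_sbar"),
    coord_phrase_rate = per100("coord_phrase"),
    adjp_rate = per100("adjp"),
    conj_vp_rate = per100("conj_vp"),
    coord_per_clause = if (counts[["clauses"]] > 0)
      as.numeric(counts[["coord_phrase"]]) / counts[["clauses"]] else NA_real_)
}
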