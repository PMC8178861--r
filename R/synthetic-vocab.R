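# Closed synthetic vocabulary for Cookie-Theft-style picture descriptions.
# The norm values are SYNTHETIC: plausible hand-assigned Zipf frequency,
# age-of-acquisition and affective values chosen so that severity-weighted
# word sampling moves the extracted norm means monotonically. They are not
# taken from any published norm set (which would need licensing); they only
# exercise the lookup code paths.

synthetic_vocab <- function() {
  # word, lemma, pos, zipf, aoa, valence, arousal, dominance
  raw <- c(
    "boy,boy,NN,5.1,3.2,6.5,4.5,5.5",
    "girl,girl,NN,5.1,3.2,6.6,4.5,5.5",
    "mother,mother,NN,5.2,2.8,7.0,4.0,6.0",
    "woman,woman,NN,5.3,3.5,6.2,4.2,5.6",
    "lady,lady,NN,4.6,4.0,6.3,4.1,5.4",
    "cookie,cookie,NN,4.3,3.0,7.4,5.0,5.2",
    "jar,jar,NN,3.8,5.5,5.0,3.5,4.8",
    "stool,stool,NN,3.2,6.0,4.8,3.4,4.6",
    "sink,sink,NN,3.9,5.0,4.7,3.3,4.7",
    "water,water,NN,5.5,2.5,6.4,3.8,5.3",
    "window,window,NN,4.8,4.0,5.6,3.2,5.0",
    "curtain,curtain,NN,3.5,6.5,5.1,3.0,4.9",
    "plate,plate,NN,4.1,4.5,5.3,3.1,5.0",
    "dish,dish,NN,4.0,4.8,5.2,3.2,5.0",
    "kitchen,kitchen,NN,4.7,3.8,5.9,3.6,5.2",
    "floor,floor,NN,4.8,4.2,5.0,3.0,4.9",
    "cupboard,cupboard,NN,3.0,6.8,4.9,3.0,4.7",
    "counter,counter,NN,3.9,6.2,4.9,3.1,4.8",
    "hand,hand,NN,5.4,2.6,5.8,3.6,5.4",
    "dishes,dish,NNS,4.0,4.8,5.2,3.2,5.0",
    "cookies,cookie,NNS,4.3,3.0,7.4,5.0,5.2",
    "is,be,VBZ,6.5,2.2,5.5,3.0,5.0",
    "are,be,VBP,6.3,2.4,5.5,3.0,5.0",
    "falls,fall,VBZ,4.4,3.6,3.4,5.6,3.8",
    "falling,fall,VBG,4.4,3.6,3.4,5.6,3.8",
    "fell,fall,VBD,4.4,3.6,3.4,5.6,3.8",
    "reaches,reach,VBZ,4.2,4.4,5.2,4.4,5.2",
    "reaching,reach,VBG,4.2,4.4,5.2,4.4,5.2",
    "reached,reach,VBD,4.2,4.4,5.2,4.4,5.2",
    "takes,take,VBZ,5.6,3.4,5.1,4.1,5.3",
    "taking,take,VBG,5.6,3.4,5.1,4.1,5.3",
    "took,take,VBD,5.6,3.4,5.1,4.1,5.3",
    "washes,wash,VBZ,4.1,3.9,5.4,3.6,5.1",
    "washing,wash,VBG,4.1,3.9,5.4,3.6,5.1",
    "washed,wash,VBD,4.1,3.9,5.4,3.6,5.1",
    "dries,dry,VBZ,3.9,4.3,5.0,3.2,5.0",
    "drying,dry,VBG,3.9,4.3,5.0,3.2,5.0",
    "dried,dry,VBD,3.9,4.3,5.0,3.2,5.0",
    "stands,stand,VBZ,4.6,3.8,5.0,3.4,5.0",
    "standing,stand,VBG,4.6,3.8,5.0,3.4,5.0",
    "stood,stand,VBD,4.6,3.8,5.0,3.4,5.0",
    "spills,spill,VBZ,3.4,4.6,3.6,5.2,3.9",
    "spilling,spill,VBG,3.4,4.6,3.6,5.2,3.9",
    "spilled,spill,VBD,3.4,4.6,3.6,5.2,3.9",
    "overflows,overflow,VBZ,2.8,7.2,3.2,5.8,3.6",
    "overflowing,overflow,VBG,2.8,7.2,3.2,5.8,3.6",
    "asks,ask,VBZ,5.0,3.3,5.3,3.8,5.1",
    "asking,ask,VBG,5.0,3.3,5.3,3.8,5.1",
    "asked,ask,VBD,5.0,3.3,5.3,3.8,5.1",
    "wants,want,VBZ,5.7,2.9,5.4,4.3,5.2",
    "the,the,DT,7.1,2.0,5.0,3.0,5.0",
    "a,a,DT,7.0,2.0,5.0,3.0,5.0",
    "this,this,DT,6.4,2.6,5.0,3.0,5.0",
    "that,that,DT,6.6,2.6,5.0,3.0,5.0",
    "these,these,DT,5.9,3.1,5.0,3.0,5.0",
    "those,those,DT,5.9,3.1,5.0,3.0,5.0",
    "he,he,PRP,6.6,2.4,5.2,3.2,5.1",
    "she,she,PRP,6.5,2.4,5.2,3.2,5.1",
    "it,it,PRP,6.9,2.2,5.0,3.0,5.0",
    "and,and,CC,7.0,2.3,5.0,3.0,5.0",
    "but,but,CC,6.5,3.0,4.8,3.2,4.9",
    "because,because,IN,6.0,3.6,5.0,3.3,5.0",
    "while,while,IN,5.5,4.6,5.0,3.1,5.0",
    "on,on,IN,6.8,2.4,5.0,3.0,5.0",
    "in,in,IN,7.0,2.3,5.0,3.0,5.0",
    "of,of,IN,7.1,2.8,5.0,3.0,5.0",
    "from,from,IN,6.5,3.2,5.0,3.0,5.0",
    "than,than,IN,6.0,4.2,5.0,3.0,5.0",
    "little,little,JJ,5.6,3.0,6.0,3.4,4.9",
    "big,big,JJ,5.6,2.9,5.8,3.9,5.4",
    "tall,tall,JJ,4.5,3.8,5.5,3.4,5.2",
    "taller,tall,JJR,3.8,4.6,5.4,3.4,5.2",
    "wet,wet,JJ,4.4,3.3,4.2,4.4,4.4",
    "full,full,JJ,5.2,3.6,5.6,3.3,5.2",
    "dirty,dirty,JJ,4.5,3.5,3.4,4.6,4.2",
    "busy,busy,JJ,4.9,4.1,4.6,4.8,4.7",
    "um,um,UH,4.0,3.0,5.0,3.0,5.0",
    "uh,uh,UH,4.0,3.0,5.0,3.0,5.0")
  m <- do.call(rbind, strsplit(raw, ",", fixed = TRUE))
  df <- data.frame(word = m[, 1], lemma = m[, 2], pos = m[, 3],
                   zipf = as.numeric(m[, 4]), aoa = as.numeric(m[, 5]),
                   valence = as.numeric(m[, 6]), arousal = as.numeric(m[, 7]),
                   dominance = as.numeric(m[, 8]), stringsAsFactors = FALSE)
  df
}

#' Synthetic psycholinguistic norms for the closed vocabulary
#'
#' Hand-assigned, plausible (but synthetic) Zipf/AoA/affective values for
#' the generator's closed Cookie-Theft vocabulary; one row per distinct
#' word form.
#'
#' @return a `norms_table`.
#' @export
synthetic_norms <- function() {
  v <- synthetic_vocab()
  df <- v[!duplicated(tolower(v$word)),
          c("word", "zipf", "aoa", "valence", "arousal", "dominance")]
  df$word <- tolower(df$word)
  rownames(df) <- NULL
  class(df) <- c("norms_table", "data.frame")
  df
}

#' Synthetic word embeddings for the closed vocabulary
#'
#' Deterministic random unit vectors per lemma (forms of the same lemma
#' share a vector with small form-specific jitter), suitable for exercising
#' embedding lookups and cosine geometry; they carry no real distributional
#' semantics.
#'
#' @param d embedding dimension (default 50).
#' @param seed RNG seed.
#' @return an `embedding_table` matrix, rownames = lower-cased word forms.
#' @export
synthetic_embeddings <- function(d = 50L, seed = 42L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- synthetic_vocab()
  v <- v[!duplicated(tolower(v$word)), , drop = FALSE]
  lemmas <- unique(v$lemma)
  base <- matrix(stats::rnorm(length(lemmas) * d), nrow = length(lemmas),
                 dimnames = list(lemmas, NULL))
  mat <- base[v$lemma, , drop = FALSE] +
    matrix(stats::rnorm(nrow(v) * d, sd = 0.05), nrow = nrow(v))
  mat <- sweep(mat, 1L, sqrt(rowSums(mat^2)), "/")
  rownames(mat) <- tolower(v$word)
  class(mat) <- c("embedding_table", class(mat))
  mat
}

#' Write synthetic norms / embeddings to the on-disk formats
#'
#' Utility to round-trip the synthetic resources through the plain-text
#' readers ([read_norms_table()], [read_embeddings()]).
#'
#' @param path output file path.
#' @param d,seed passed to [synthetic_embeddings()].
#' @return `path`, invisibly.
#' @export
write_synthetic_norms <- function(path) {
  utils::write.table(as.data.frame(synthetic_norms()), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_synthetic_norms
#' @export
write_synthetic_embeddings <- function(path, d = 50L, seed = 42L) {
  emb <- synthetic_embeddings(d = d, seed = seed)
  lines <- vapply(seq_len(nrow(emb)), function(i) {
    paste(c(rownames(emb)[i], format(emb[i, ], digits = 8, trim = TRUE)),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
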