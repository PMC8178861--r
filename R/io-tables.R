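#' Read a psycholinguistic norms table
#'
#' Expects a TSV with header `word, zipf, aoa, valence, arousal, dominance`.
#' Zipf is a log-scale frequency norm; age of acquisition (aoa) is in years;
#' valence/arousal/dominance are affective norms on a 1-9 scale. Lookups are
#' case-folded. Blank cells are missing values and stay missing: a word absent
#' from the table reports `NA`, never 0, so norm means are computed only over
#' covered tokens.
#'
#' @param path TSV path or connection.
#' @return an object of class `norms_table` (a data frame keyed by
#'   lower-cased word).
#' @export
read_norms_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("word", "zipf", "aoa", "valence", "arousal", "dominance")
  if (!all(need %in% names(df))) {
    stop("norms table must have header columns: ", paste(need, collapse = ", "))
  }
  df$word <- tolower(df$word)
  if (anyDuplicated(df$word)) {
    warning("duplicate words in norms table; last row wins")
    df <- df[!duplicated(df$word, fromLast = TRUE), , drop = FALSE]
  }
  for (col in need[-1]) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  class(df) <- c("norms_table", "data.frame")
  df
}

#' Look up norm values for words
#'
#' @param norms a `norms_table`.
#' @param words character vector; matched case-insensitively.
#' @return a data frame with one row per query word; `NA` rows for words not
#'   in the table, and a `covered` logical column.
#' @export
norms_lookup <- function(norms, words) {
  i <- match(tolower(words), norms$word)
  out <- norms[ifelse(is.na(i), NA_integer_, i),
               c("zipf", "aoa", "valence", "arousal", "dominance"), drop = FALSE]
  rownames(out) <- NULL
  out$word <- words
  out$covered <- !is.na(i)
  out
}

#' Read a GloVe-style word-embedding table
#'
#' Whitespace-delimited text, one word per line followed by its vector
#' components. The dimensionality is inferred from the first line; any line
#' with a different dimension or a non-numeric component is an error. Zero
#' vectors are rejected (they have no direction for cosine similarity).
#'
#' @param path text file path or connection.
#' @return a numeric matrix with one row per word, rownames = lower-cased
#'   words, of class `embedding_table`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("embedding table is empty")
  parts <- strsplit(trimws(lines), "\\s+")
  d <- length(parts[[1L]]) - 1L
  if (d < 1L) stop("embedding line 1 has no vector components")
  mat <- matrix(NA_real_, nrow = length(parts), ncol = d)
  words <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) - 1L != d) {
      stop("embedding line ", i, " has dimension ", length(p) - 1L,
           " but dimension ", d, " was inferred from line 1")
    }
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v)) stop("non-numeric embedding component on line ", i)
    if (all(v == 0)) stop("zero embedding vector on line ", i, " ('", p[1L], "')")
    words[i] <- tolower(p[1L])
    mat[i, ] <- v
  }
  rownames(mat) <- words
  class(mat) <- c("embedding_table", class(mat))
  mat
}

#' Read a clinician rating panel
#'
#' Long-format CSV with columns `sample_id, characteristic, rater_id, rating`;
#' ratings are ordinal 0-3 (0 = finding not present, 3 = severe). Any value
#' outside `{0,1,2,3}` is a validation error naming the offending cell.
#'
#' @param path CSV path or connection.
#' @return a `rating_panel`: the validated long data frame.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "characteristic", "rater_id", "rating")
  if (!all(need %in% names(df))) {
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "))
  }
  rating_panel(df)
}

#' Construct and validate a rating panel
#'
#' @param df data frame with columns `sample_id`, `characteristic`,
#'   `rater_id`, `rating`.
#' @return the data frame with class `rating_panel`.
#' @export
rating_panel <- function(df) {
  df$rating <- suppressWarnings(as.numeric(df$rating))
  bad <- which(is.na(df$rating) | !(df$rating %in% 0:3))
  if (length(bad)) {
    i <- bad[1L]
    stop("invalid rating for sample '", df$sample_id[i], "', characteristic '",
         df$characteristic[i], "', rater '", df$rater_id[i],
         "': ratings must be integers in 0..3")
  }
  df$rating <- as.integer(df$rating)
  class(df) <- c("rating_panel", "data.frame")
  df
}

# items x raters integer matrix for one characteristic
panel_matrix <- function(panel, characteristic = NULL) {
  df <- as.data.frame(panel)
  if (!is.null(characteristic)) df <- df[df$characteristic == characteristic, , drop = FALSE]
  if (!nrow(df)) stop("no ratings for characteristic '", characteristic, "'")
  items <- if (length(unique(df$characteristic)) > 1L) {
    paste(df$sample_id, df$characteristic, sep = "|")
  } else df$sample_id
  m <- tapply(df$rating, list(items, df$rater_id), function(x) x[length(x)])
  storage.mode(m) <- "double"
  m
}

#' Read diagnosis labels
#'
#' CSV with columns `sample_id, group`; groups are `HC` (healthy control),
#' `MCI`, `AD`.
#'
#' @param path CSV path or connection.
#' @return data frame with `sample_id` and `group` (factor HC/MCI/AD).
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("labels CSV must have columns sample_id, group")
  }
  bad <- setdiff(unique(df$group), c("HC", "MCI", "AD"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = c("HC", "MCI", "AD"))
  df
}

#' Read a picture content lexicon
#'
#' TSV with columns `word, role, synonyms`; `role` is one of
#' `subject, object, place, action` and `synonyms` is a `|`-separated list.
#' The package ships a default lexicon for the Cookie Theft stimulus under
#' `inst/extdata/cookie_theft_lexicon.tsv`; it is fully user-replaceable.
#'
#' @param path TSV path; defaults to the shipped Cookie Theft lexicon.
#' @return data frame with columns `word`, `role`, `synonyms` (list column).
#' @export
read_content_lexicon <- function(path = system.file("extdata",
                                                    "cookie_theft_lexicon.tsv",
                                                    package = "speechmarker")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("word", "role") %in% names(df))) {
    stop("content lexicon must have columns word, role")
  }
  ok <- c("subject", "object", "place", "action")
  if (!all(df$role %in% ok)) stop("lexicon roles must be one of: ", paste(ok, collapse = ", "))
  df$word <- tolower(df$word)
  syn <- if ("synonyms" %in% names(df)) df$synonyms else NA_character_
  df$synonyms <- lapply(syn, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else tolower(strsplit(s, "|", fixed = TRUE)[[1L]])
  })
  df
}
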