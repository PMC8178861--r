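#' Spearman screen of features against consensus ratings
#'
#' For each feature, Spearman's rho is computed against the consensus rating
#' over samples with both values present (average ranks on ties) and tested
#' two-sided via the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom.
#' Selection is at unadjusted `alpha` (no multiplicity correction, mirroring
#' a deliberately liberal screening step); an optional Benjamini-Hochberg
#' flag adjusts the p-values before selection.
#'
#' @param features samples x features data frame or matrix.
#' @param consensus numeric vector of consensus ratings, aligned with the
#'   rows of `features` (or named by sample id).
#' @param alpha selection level (default 0.05).
#' @param min_pairs minimum complete pairs per feature (default 4; features
#'   with fewer, and constant features, are skipped with a warning).
#' @param bh apply Benjamini-Hochberg adjustment before selecting.
#' @return data frame: `feature`, `rho`, `p_value`, `n_used`, `selected`.
#' @export
spearman_screen <- function(features, consensus, alpha = 0.05,
                            min_pairs = 4L, bh = FALSE) {
  fm <- as.data.frame(features)
  if (!is.null(names(consensus)) && !is.null(rownames(fm)) &&
      all(rownames(fm) %in% names(consensus))) {
    consensus <- consensus[rownames(fm)]
  }
  stopifnot(length(consensus) == nrow(fm))
  skipped <- character(0)
  res <- lapply(names(fm), function(f) {
    x <- as.numeric(fm[[f]])
    ok <- !is.na(x) & !is.na(consensus)
    n <- sum(ok)
    if (n < min_pairs || length(unique(x[ok])) < 2L ||
        length(unique(consensus[ok])) < 2L) {
      skipped <<- c(skipped, f)
      return(NULL)
    }
    rho <- stats::cor(rank(x[ok]), rank(consensus[ok]))
    p <- spearman_p(rho, n)
    data.frame(feature = f, rho = rho, p_value = p, n_used = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (length(skipped)) {
    warning(length(skipped), " feature(s) skipped (constant or < ", min_pairs,
            " complete pairs)")
  }
  if (is.null(res)) {
    warning("no feature had enough complete pairs to screen")
    return(data.frame(feature = character(), rho = numeric(),
                      p_value = numeric(), n_used = integer(),
                      selected = logical(), stringsAsFactors = FALSE))
  }
  p_sel <- if (bh) stats::p.adjust(res$p_value, "BH") else res$p_value
  res$selected <- p_sel < alpha
  res[order(-abs(res$rho)), , drop = FALSE]
}

# two-sided p for Spearman rho via the t approximation
spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
}

#' Between-group odds ratio of impairment
#'
#' Dichotomises the consensus rating at `impaired_threshold` (default:
#' any rating >= 1, i.e. the finding is present at all) and forms the 2x2
#' group x impaired table for groups `A` vs `B`. When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells. The 95% CI is the
#' Woolf log-scale interval \eqn{\exp(\log OR \pm 1.96 \sqrt{\sum 1/cell})}.
#' The printed OR is the odds of impairment in `A` relative to `B`.
#'
#' @param consensus `consensus_ratings` data frame (or numeric vector named
#'   by sample id).
#' @param labels data frame `sample_id`, `group`.
#' @param A,B group labels to compare (e.g. `"AD"`, `"HC"`).
#' @param impaired_threshold consensus at or above which a sample counts as
#'   impaired.
#' @return list of class `odds_ratio_result`: `groups`, `table`,
#'   `or_estimate`, `ci95`, `corrected`.
#' @export
group_odds_ratio <- function(consensus, labels, A, B, impaired_threshold = 1) {
  cons <- if (is.data.frame(consensus)) {
    stats::setNames(consensus$consensus, consensus$item)
  } else consensus
  get_group <- function(g) {
    ids <- labels$sample_id[labels$group == g]
    v <- cons[intersect(ids, names(cons))]
    v <- v[!is.na(v)]
    if (!length(v)) stop("group '", g, "' has no consensus ratings")
    v
  }
  va <- get_group(A); vb <- get_group(B)
  a <- sum(va >= impaired_threshold); b <- sum(va < impaired_threshold)
  c_ <- sum(vb >= impaired_threshold); d <- sum(vb < impaired_threshold)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c(A, B), c("impaired", "not_impaired")))
  corrected <- any(tab == 0)
  w <- if (corrected) tab + 0.5 else tab
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  se <- sqrt(sum(1 / w))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  structure(list(groups = c(A, B), table = tab, or_estimate = or,
                 ci95 = ci, corrected = corrected,
                 impaired_threshold = impaired_threshold),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR(%s vs %s) = %.2f, 95%% CI %.2f-%.2f%s\n",
              x$groups[1], x$groups[2], x$or_estimate, x$ci95[1], x$ci95[2],
              if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}
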