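#' Modal consensus from a multi-rater ordinal panel
#'
#' Per item, the consensus is the modal rating across raters. A multimodal
#' tie is broken toward the value nearest the item mean; a remaining tie
#' goes to the lower severity. Items where raters disagree by 2 or more
#' points (max - min >= 2) are flagged for re-rating: a second-round panel
#' can be supplied whose ratings replace the flagged items before the modes
#' are recomputed.
#'
#' @param panel a `rating_panel` (long data frame) or items x raters matrix.
#' @param characteristic optional characteristic to subset a long panel.
#' @param second_round optional panel of re-ratings for flagged items, same
#'   shape conventions.
#' @return a data frame of class `consensus_ratings`: `item`, `consensus`,
#'   `flagged`, `n_raters_used`.
#' @export
consensus_rating <- function(panel, characteristic = NULL, second_round = NULL) {
  m <- if (is.matrix(panel)) panel else panel_matrix(panel, characteristic)
  mode_one <- function(x) {
    x <- x[!is.na(x)]
    tab <- table(x)
    cands <- as.numeric(names(tab)[tab == max(tab)])
    if (length(cands) > 1L) {
      d <- abs(cands - mean(x))
      cands <- cands[d == min(d)]
    }
    min(cands)
  }
  n_used <- rowSums(!is.na(m))
  if (any(n_used < 2L)) {
    stop("consensus needs >= 2 raters per item (item '",
         rownames(m)[which(n_used < 2L)[1L]], "')")
  }
  rng <- apply(m, 1L, function(x) diff(range(x, na.rm = TRUE)))
  flagged <- rng >= 2
  if (!is.null(second_round)) {
    m2 <- if (is.matrix(second_round)) second_round
          else panel_matrix(second_round, characteristic)
    redo <- intersect(rownames(m)[flagged], rownames(m2))
    m[redo, colnames(m2)] <- m2[redo, , drop = FALSE]
    rng <- apply(m, 1L, function(x) diff(range(x, na.rm = TRUE)))
    flagged <- rng >= 2
    n_used <- rowSums(!is.na(m))
  }
  out <- data.frame(item = rownames(m),
                    consensus = apply(m, 1L, mode_one),
                    flagged = unname(flagged),
                    n_raters_used = unname(n_used),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("consensus_ratings", "data.frame")
  out
}

#' Two-way random-effects intraclass correlation
#'
#' Shrout-Fleiss ICC(2,1) (single rater, absolute agreement) and ICC(2,k)
#' (average of k raters) from the two-way mean squares of a complete
#' items x raters panel:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n}}
#' with the F test MS_R/MS_E on (n-1), (n-1)(k-1) degrees of freedom.
#' Agreement bands follow the conventional thresholds: < 0.5 poor,
#' 0.5-0.75 moderate, 0.75-0.9 good, >= 0.9 excellent (boundary values go to
#' the higher band).
#'
#' @param panel `rating_panel` or items x raters numeric matrix; items with
#'   any missing rating are dropped with a warning.
#' @param characteristic optional characteristic to subset a long panel.
#' @return list of class `icc_result`: `icc_single`, `icc_average`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `band`, `n_items`, `n_raters`.
#' @export
icc <- function(panel, characteristic = NULL) {
  m <- if (is.matrix(panel)) panel else panel_matrix(panel, characteristic)
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sum(!complete), " item(s) with missing ratings dropped")
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("ICC needs at least 2 complete items")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  f <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  band <- if (icc1 >= 0.9) "excellent" else if (icc1 >= 0.75) "good"
          else if (icc1 >= 0.5) "moderate" else "poor"
  structure(list(icc_single = icc1, icc_average = icck, f_stat = f,
                 df1 = df1, df2 = df2, p_value = p, band = band,
                 n_items = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f, ICC(2,%d) = %.3f [%s], F(%d,%d) = %.2f, p = %.3g\n",
              x$icc_single, x$n_raters, x$icc_average, x$band,
              x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}
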