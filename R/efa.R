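# Exploratory factor analysis: Horn's parallel analysis for factor retention,
# iterated principal-axis extraction, and direct-oblimin (quartimin) rotation
# by the oblique gradient-projection algorithm.

#' Horn's parallel analysis
#'
#' Compares the eigenvalues of the observed p x p Pearson correlation matrix
#' against the position-wise `percentile` of eigenvalues from `n_iter`
#' correlation matrices of iid standard-normal data of the same n x p shape.
#' The retained factor count k is the length of the initial run of positions
#' where the observed eigenvalue exceeds its threshold (stopping at the
#' first failure). This is Horn's original full-correlation-matrix variant.
#'
#' @param data n x p numeric matrix or data frame.
#' @param n_iter number of random datasets (default 100).
#' @param percentile threshold percentile (default 95).
#' @param seed RNG seed for the random eigenvalue draws.
#' @return list of class `parallel_analysis`: `k`, `eigen_observed`,
#'   `eigen_thresholds`.
#' @export
parallel_analysis <- function(data, n_iter = 100L, percentile = 95, seed = 1L) {
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L || p < 2L) stop("parallel analysis needs n >= 3 and p >= 2")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    stop("constant column: ", paste(colnames(x)[sds == 0 | is.na(sds)],
                                    collapse = ", "))
  }
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sims <- matrix(NA_real_, nrow = n_iter, ncol = p)
  for (i in seq_len(n_iter)) {
    z <- matrix(stats::rnorm(n * p), nrow = n)
    sims[i, ] <- eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
  }
  # quantile type 6 is the exceedance-calibrated estimator: for m iterations
  # P(new draw > estimate) = 1 - p exactly, so "greater than the 95th
  # percentile" retains a null eigenvalue at the nominal 5% rate
  thr <- apply(sims, 2L, stats::quantile, probs = percentile / 100, type = 6)
  above <- obs > thr
  k <- if (above[1L]) which.min(c(above, FALSE)) - 1L else 0L
  structure(list(k = as.integer(k), eigen_observed = obs,
                 eigen_thresholds = unname(thr)),
            class = "parallel_analysis")
}

# save/restore the global RNG state so seeded subroutines do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Iterated principal-axis factoring
#'
#' Extracts `k` common factors from a correlation matrix by iterating the
#' eigendecomposition of the reduced correlation matrix (communalities on
#' the diagonal). Initial communalities are squared multiple correlations,
#' `1 - 1/diag(solve(R))`; for singular R (e.g. p > n) the Moore-Penrose
#' pseudoinverse is used, falling back to the maximum absolute off-diagonal
#' correlation per row. Iteration stops when communalities change by less
#' than `tol` or after `max_iter` sweeps; communalities are clamped at 0.995
#' to contain Heywood cases.
#'
#' @param R correlation matrix (symmetric, unit diagonal).
#' @param k number of factors (>= 1).
#' @param max_iter,tol iteration controls.
#' @return list: `loadings` (p x k, unrotated), `communalities`,
#'   `converged`, `iterations`.
#' @export
principal_axis_factor <- function(R, k, max_iter = 200L, tol = 1e-4) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(k >= 1L, nrow(R) == p)
  h2 <- smc_communalities(R)
  converged <- FALSE
  iter <- 0L
  loadings <- NULL
  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(k)], 0)
    loadings <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
    h2_new <- pmin(rowSums(loadings^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  rownames(loadings) <- rownames(R)
  list(loadings = loadings, communalities = h2, converged = converged,
       iterations = iter)
}

smc_communalities <- function(R) {
  p <- ncol(R)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) <= 0)) {
    inv <- tryCatch(MASS::ginv(R), error = function(e) NULL)
  }
  if (!is.null(inv) && all(is.finite(diag(inv))) && all(diag(inv) > 0)) {
    h2 <- 1 - 1 / diag(inv)
    if (all(h2 > 0 & h2 < 1)) return(h2)
  }
  # fallback: largest absolute off-diagonal correlation per row
  offdiag <- abs(R); diag(offdiag) <- 0
  apply(offdiag, 1L, max)
}

# quartimin criterion (direct oblimin with gamma = 0) and its gradient
oblimin_criterion <- function(L, gamma = 0) {
  k <- ncol(L); p <- nrow(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  M <- if (gamma == 0) L2 else (diag(p) - matrix(gamma / p, p, p)) %*% L2
  f <- sum(L2 * (M %*% N)) / 4
  Gq <- L * (M %*% N)
  list(f = f, Gq = Gq)
}

#' Direct-oblimin rotation by oblique gradient projection
#'
#' Rotates an unrotated loading matrix to a direct-oblimin (`gamma = 0`,
#' i.e. quartimin) solution using the oblique gradient-projection algorithm,
#' restarting from `n_starts` random seeded rotation matrices and keeping
#' the solution with the lowest criterion. Afterwards each factor's sign is
#' flipped so its largest-|loading| is positive, and factors are ordered by
#' explained variance (pattern sum of squares), descending. For `k = 1` the
#' rotation is the identity.
#'
#' @param loadings p x k unrotated loading matrix.
#' @param n_starts random restarts (default 30).
#' @param seed RNG seed for the restarts.
#' @param gamma oblimin gamma (0 = quartimin).
#' @param max_iter,eps gradient-projection controls.
#' @return list: `pattern`, `structure`, `phi` (factor correlations),
#'   `converged`.
#' @export
oblimin_rotate <- function(loadings, n_starts = 30L, seed = 1L, gamma = 0,
                           max_iter = 500L, eps = 1e-6) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k < 2L) {
    pat <- flip_sign(A)
    return(list(pattern = pat, structure = pat, phi = matrix(1, 1, 1),
                converged = TRUE))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  starts <- c(list(diag(k)), replicate(n_starts - 1L, {
    T0 <- matrix(stats::rnorm(k * k), k, k)
    sweep(T0, 2L, sqrt(colSums(T0^2)), "/")
  }, simplify = FALSE))
  for (T0 in starts) {
    sol <- gpa_oblique(A, T0, gamma = gamma, max_iter = max_iter, eps = eps)
    if (is.null(best) || sol$f < best$f) best <- sol
  }
  pat <- best$loadings
  phi <- best$phi
  # sign convention and variance ordering
  signs <- vapply(seq_len(k), function(j) {
    v <- pat[, j]; s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  }, numeric(1))
  pat <- sweep(pat, 2L, signs, "*")
  phi <- diag(signs) %*% phi %*% diag(signs)
  ord <- order(colSums(pat^2), decreasing = TRUE)
  pat <- pat[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  dimnames(phi) <- NULL
  colnames(pat) <- paste0("F", seq_len(k))
  list(pattern = pat, structure = pat %*% phi, phi = phi,
       converged = best$converged)
}

# oblique gradient-projection (Jennrich): minimise the rotation criterion
# over oblique rotation matrices with unit-length columns
gpa_oblique <- function(A, Tmat, gamma = 0, max_iter = 500L, eps = 1e-6) {
  al <- 1
  L <- A %*% t(solve(Tmat))
  vg <- oblimin_criterion(L, gamma)
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  f <- vg$f
  converged <- FALSE
  Tt <- Tmat
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    improved <- FALSE
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
      Lt <- A %*% t(solve(Tt))
      vgt <- oblimin_criterion(Lt, gamma)
      if (vgt$f < f - 0.5 * s^2 * al) { improved <- TRUE; break }
      al <- al / 2
    }
    if (!improved) break
    Tmat <- Tt
    L <- Lt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tmat))
  }
  list(loadings = L, phi = t(Tmat) %*% Tmat, f = f, converged = converged)
}

flip_sign <- function(L) {
  s <- vapply(seq_len(ncol(L)), function(j) {
    v <- L[, j]; sg <- sign(v[which.max(abs(v))]); if (sg == 0) 1 else sg
  }, numeric(1))
  sweep(L, 2L, s, "*")
}

#' Run a full exploratory factor analysis
#'
#' Standardises the columns, retains k factors by parallel analysis,
#' extracts by iterated principal axes, rotates by direct oblimin, and
#' assigns each variable to the factor with its largest absolute pattern
#' loading among factors where that loading reaches `cutoff` (0.6 by
#' default, conservative for small samples); variables below the cutoff on
#' every factor stay unassigned, so each variable appears in at most one
#' factor column. The variance proportion of factor j is the pattern sum of
#' squares over p, in percent; with oblique factors these proportions need
#' not sum to the total common variance.
#'
#' @param features samples x variables data frame or matrix (already
#'   restricted to screened variables); rows with missing values are dropped.
#' @param cutoff loading cutoff for factor assignment.
#' @param n_iter,percentile parallel-analysis settings.
#' @param seed RNG seed (parallel analysis and rotation restarts).
#' @return list of class `efa_result`: `k`, `pattern`, `structure`, `phi`,
#'   `communalities`, `var_prop` (percent), `assignments`,
#'   `eigen_observed`, `eigen_thresholds`, `converged`, `n`, `variables`.
#' @export
run_efa <- function(features, cutoff = 0.6, n_iter = 100L, percentile = 95,
                    seed = 1L) {
  x <- as.matrix(as.data.frame(features))
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (!ncol(x)) stop("no variables to analyse")
  p <- ncol(x)
  x <- scale(x)
  pa <- parallel_analysis(x, n_iter = n_iter, percentile = percentile,
                          seed = seed)
  vars <- colnames(x)
  if (pa$k == 0L) {
    return(structure(list(k = 0L, pattern = NULL, structure = NULL,
                          phi = NULL, communalities = NULL,
                          var_prop = numeric(0),
                          assignments = stats::setNames(rep(NA_integer_, p), vars),
                          eigen_observed = pa$eigen_observed,
                          eigen_thresholds = pa$eigen_thresholds,
                          converged = TRUE, n = nrow(x), variables = vars),
                     class = "efa_result"))
  }
  R <- stats::cor(x)
  if (nrow(x) < p) {
    warning("fewer samples (", nrow(x), ") than variables (", p,
            "): correlation matrix is singular; pseudoinverse SMCs used")
  }
  paf <- principal_axis_factor(R, pa$k)
  rot <- oblimin_rotate(paf$loadings, seed = seed)
  pat <- rot$pattern
  rownames(pat) <- vars
  assignments <- apply(pat, 1L, function(v) {
    ok <- which(abs(v) >= cutoff)
    if (!length(ok)) return(NA_integer_)
    ok[which.max(abs(v)[ok])][1L]
  })
  # ties on |loading| resolve to the lower factor index via which.max
  var_prop <- colSums(pat^2) / p * 100
  structure(list(k = pa$k, pattern = pat, structure = rot$structure,
                 phi = rot$phi, communalities = paf$communalities,
                 var_prop = unname(var_prop),
                 assignments = assignments,
                 eigen_observed = pa$eigen_observed,
                 eigen_thresholds = pa$eigen_thresholds,
                 converged = paf$converged && rot$converged,
                 n = nrow(x), variables = vars),
            class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf("<efa_result: %d factor(s), %d variables, n = %d>\n",
              x$k, length(x$variables), x$n))
  if (x$k > 0L) {
    cat("variance explained (%):", paste(sprintf("%.1f", x$var_prop),
                                         collapse = ", "), "\n")
    cat(sum(!is.na(x$assignments)), "variable(s) assigned at cutoff\n")
  }
  invisible(x)
}

#' Tucker congruence between loading matrices
#'
#' Column-wise Tucker congruence coefficients after greedily aligning the
#' columns of `B` to those of `A` by absolute congruence (sign is ignored).
#' Used to assess factor recovery in simulations.
#'
#' @param A,B p x k loading matrices.
#' @return numeric vector of per-factor congruence coefficients (absolute).
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  k <- ncol(A)
  cong <- abs(crossprod(A, B) /
                outer(sqrt(colSums(A^2)), sqrt(colSums(B^2))))
  out <- numeric(k)
  used <- integer(0)
  for (j in seq_len(k)) {
    row <- cong[j, ]
    row[used] <- -Inf
    pick <- which.max(row)
    out[j] <- cong[j, pick]
    used <- c(used, pick)
  }
  out
}
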