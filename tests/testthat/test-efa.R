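test_that("two perfectly correlated columns always retain a factor", {
  set.seed(8)
  z <- rnorm(50)
  pa <- parallel_analysis(cbind(z, z + 1e-10 * rnorm(50)), seed = 1)
  expect_gte(pa$k, 1L)
  expect_equal(pa$eigen_observed[1], 2, tolerance = 1e-6)
})

test_that("parallel analysis rejects constant columns and tiny inputs", {
  x <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(parallel_analysis(x), "constant column: b")
  expect_error(parallel_analysis(matrix(rnorm(4), 2)), "n >= 3")
})

test_that("PA thresholds decrease in position and k is stable in n_iter", {
  lam <- matrix(0, 12, 2)
  lam[1:6, 1] <- 0.8; lam[7:12, 2] <- 0.8
  x <- simulate_factor_model(lam, n = 500, seed = 30)
  pa100 <- parallel_analysis(x, n_iter = 100, seed = 2)
  pa1000 <- parallel_analysis(x, n_iter = 1000, seed = 2)
  expect_true(all(diff(pa100$eigen_thresholds) < 0))
  expect_equal(pa100$k, pa1000$k)
  expect_equal(pa100$k, 2L)
})

test_that("principal axes: identity matrix has no common factor", {
  paf <- principal_axis_factor(diag(6), 1)
  expect_lt(max(abs(paf$loadings)), 1e-6)
})

test_that("one-factor structure with uniform loadings is recovered", {
  p <- 6; l <- 0.7
  R <- matrix(l^2, p, p); diag(R) <- 1
  paf <- principal_axis_factor(R, 1)
  expect_equal(abs(as.vector(paf$loadings)), rep(l, p), tolerance = 0.01)
  expect_true(paf$converged)
})

test_that("singular correlation matrices (p > n) run via pseudoinverse SMCs", {
  set.seed(14)
  x <- matrix(rnorm(30 * 31), nrow = 30)
  R <- cor(x)
  paf <- principal_axis_factor(R, 2)
  expect_true(all(is.finite(paf$loadings)))
  expect_true(all(paf$communalities <= 0.995 + 1e-12))
})

test_that("k = 1 rotation is the identity with phi = 1", {
  A <- matrix(c(0.8, 0.7, 0.6), ncol = 1)
  rot <- oblimin_rotate(A)
  expect_equal(unname(rot$pattern), A)
  expect_equal(rot$phi, matrix(1, 1, 1))
})

test_that("rotation preserves the reproduced reduced correlation matrix", {
  lam <- matrix(0, 10, 2)
  lam[1:5, 1] <- 0.75; lam[6:10, 2] <- 0.75
  x <- simulate_factor_model(lam, n = 400, seed = 21)
  paf <- principal_axis_factor(cor(x), 2)
  rot <- oblimin_rotate(paf$loadings, seed = 3)
  reproduced <- rot$pattern %*% rot$phi %*% t(rot$pattern)
  expect_lt(max(abs(reproduced - tcrossprod(paf$loadings))), 1e-6)
  # communalities from pattern/phi equal the PAF communalities
  expect_equal(unname(diag(reproduced)), unname(paf$communalities),
               tolerance = 1e-4)
})

test_that("an ideal orthogonal two-factor pattern is recovered", {
  A <- rbind(matrix(c(0.8, 0), 6, 2, byrow = TRUE),
             matrix(c(0, 0.8), 6, 2, byrow = TRUE))
  # rotate into an arbitrary mix, then ask oblimin to undo it
  theta <- 0.4
  mix <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rot <- oblimin_rotate(A %*% mix, seed = 9)
  cong <- tucker_congruence(A, rot$pattern)
  expect_true(all(cong > 0.99))
  expect_lt(max(abs(rot$phi[1, 2])), 0.15)
})

test_that("run_efa assigns simple-structure variables to their factors", {
  lam <- matrix(0, 12, 2)
  lam[1:6, 1] <- 0.8; lam[7:12, 2] <- 0.8
  x <- simulate_factor_model(lam, phi = matrix(c(1, 0.3, 0.3, 1), 2),
                             n = 500, seed = 51)
  colnames(x) <- paste0("v", 1:12)
  res <- run_efa(x, seed = 4)
  expect_equal(res$k, 2L)
  f_first <- res$assignments[["v1"]]
  expect_true(all(res$assignments[1:6] == f_first))
  expect_true(all(res$assignments[7:12] == 3L - f_first))
  expect_true(all(res$var_prop > 0))
  # a full rerun with the same seed is identical
  expect_identical(res, run_efa(x, seed = 4))
})

test_that("variables below the cutoff stay unassigned", {
  lam <- cbind(c(rep(0.8, 5), 0.45), c(0, 0, 0, 0, 0, 0))
  x <- simulate_factor_model(lam[, 1, drop = FALSE], n = 600, seed = 77)
  # force the last column to load weakly by diluting with noise
  colnames(x) <- paste0("v", 1:6)
  res <- run_efa(x, cutoff = 0.6, seed = 5)
  expect_equal(res$k, 1L)
  if (abs(res$pattern["v6", 1]) < 0.6) {
    expect_true(is.na(res$assignments[["v6"]]))
  }
  expect_true(all(!is.na(res$assignments[paste0("v", 1:5)])))
})

test_that("k = 0 on pure noise yields an empty factor solution", {
  set.seed(66)
  x <- matrix(rnorm(300 * 8), ncol = 8)
  colnames(x) <- paste0("v", 1:8)
  res <- run_efa(x, seed = 6)
  if (res$k == 0L) {
    expect_true(all(is.na(res$assignments)))
    expect_length(res$var_prop, 0)
  } else {
    succeed("parallel analysis retained a factor on this draw")
  }
})

test_that("simulated factor data matches its implied correlation at large n", {
  lam <- matrix(0, 6, 2)
  lam[1:3, 1] <- 0.7; lam[4:6, 2] <- 0.7
  phi <- matrix(c(1, 0.4, 0.4, 1), 2)
  x <- simulate_factor_model(lam, phi = phi, n = 20000, seed = 13)
  implied <- lam %*% phi %*% t(lam); diag(implied) <- 1
  expect_lt(max(abs(cor(x) - implied)), 0.03)
  expect_identical(x, simulate_factor_model(lam, phi = phi, n = 20000, seed = 13))
  expect_error(simulate_factor_model(matrix(1.2, 3, 1), n = 10), "uniqueness")
})

test_that("zero loadings give iid standardised columns", {
  x <- simulate_factor_model(matrix(0, 5, 1), n = 5000, seed = 2)
  off <- cor(x); diag(off) <- 0
  expect_lt(max(abs(off)), 0.05)
  expect_equal(unname(colMeans(x)), rep(0, 5), tolerance = 1e-10)
})
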