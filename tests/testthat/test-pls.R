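make_candidates <- function(n, n_seq, M, seed) {
  set.seed(seed)
  array(rnorm(n * n_seq * M), c(n, n_seq, M))
}

test_that("skew filter excludes heavy-tailed measures before ranking", {
  set.seed(121)
  n <- 60
  cand <- make_candidates(n, 6, 40, 121)
  skewed <- exp(rnorm(n) * 1.5)            # |skewness| > 1
  for (q in 1:6) cand[, q, 7] <- skewed
  B <- matrix(rnorm(n * 5), n, 5)
  sel <- select_features(cand, B, "correlation", k = 10)
  expect_true(7L %in% sel$skew_excluded)
  expect_false(7L %in% sel$indices)
})

test_that("correlation selection matches an exhaustive oracle", {
  set.seed(122)
  n <- 80
  cand <- make_candidates(n, 6, 200, 122)
  B <- matrix(rnorm(n * 26), n, 26)
  sel <- select_features(cand, B, "correlation", k = 30)
  # brute force: all 200 x 26 correlations of sequence means
  mm <- apply(cand, c(1, 3), mean)
  sk <- apply(mm, 2, e1071::skewness, type = 2)
  pool <- which(abs(sk) <= 1)
  score <- apply(abs(cor(mm, B)), 1, max)
  oracle <- pool[order(-score[pool], pool)][1:30]
  expect_equal(sel$indices, oracle)
  # a perfectly correlated feature ranks first
  cand2 <- cand
  for (q in 1:6) cand2[, q, 50] <- B[, 3]
  sel2 <- select_features(cand2, B, "correlation", k = 5)
  expect_equal(sel2$indices[1L], 50L)
})

test_that("icc and combined methods use reliability rankings", {
  set.seed(123)
  n <- 50; M <- 30
  subj <- matrix(rnorm(n * M), n, M)
  rel <- seq(0.1, 2, length.out = M)       # increasing reliability
  cand <- array(NA_real_, c(n, 6, M))
  for (q in 1:6)
    cand[, q, ] <- sweep(subj, 2, rel, "*") + matrix(rnorm(n * M), n, M)
  B <- matrix(rnorm(n * 4), n, 4)
  sel <- select_features(cand, B, "icc", k = 5)
  expect_gt(mean(sel$indices), M - 8)      # top-reliability indices
  selc <- select_features(cand, B, "combined", k = 5)
  expect_equal(length(selc$indices), 5L)
})

test_that("dynamic selection returns high-minus-low sequence change scores", {
  set.seed(124)
  n <- 60
  cand <- make_candidates(n, 6, 20, 124)
  B <- matrix(rnorm(n * 3), n, 3)
  # feature 4 correlates with behavior 2 only in sequence 6
  cand[, 6, 4] <- B[, 2] + rnorm(n, sd = 0.4)
  sel <- select_features(cand, B, "dynamic", k = 3)
  expect_true(4L %in% sel$indices)
  i <- which(sel$indices == 4L)
  expect_equal(sel$values[, i],
               cand[, sel$hi_seq[i], 4] - cand[, sel$lo_seq[i], 4])
})

test_that("frozen selections transfer to a test cohort unchanged", {
  cand_tr <- make_candidates(50, 6, 40, 125)
  cand_te <- make_candidates(50, 6, 40, 126)
  B <- matrix(rnorm(50 * 5), 50, 5)
  sel <- select_features(cand_tr, B, "correlation", k = 10)
  vals <- apply_selection(sel, cand_te)
  expect_equal(dim(vals), c(50L, 10L))
  expect_equal(vals[, 1], apply(cand_te[, , sel$indices[1]], 1, mean))
})

test_that("PLS identity coupling and planted cross-structure recovery", {
  set.seed(127)
  X <- matrix(rnorm(100 * 10), 100, 10)
  f <- pls_fit(X, X, n_comp = 4)
  expect_equal(f$score_correlations[1L], 1, tolerance = 1e-10)
  expect_error(pls_fit(cbind(X, 0), X), "constant")
  # planted two-factor cross-structure at large n
  n <- 2000
  F2 <- matrix(rnorm(n * 2), n, 2)
  Lx <- matrix(rnorm(2 * 15), 2, 15)
  Ly <- matrix(rnorm(2 * 12), 2, 12)
  Xp <- F2 %*% Lx + matrix(rnorm(n * 15, sd = 0.8), n, 15)
  Yp <- F2 %*% Ly + matrix(rnorm(n * 12, sd = 0.8), n, 12)
  fit <- pls_fit(Xp, Yp, n_comp = 4)
  # the top-2 salience subspace spans each planted loading pattern
  # (expressed on the standardized-column scale PLS operates on)
  for (k in 1:2) {
    lk <- Lx[k, ] / apply(Xp, 2, sd)
    r2 <- summary(lm(lk ~ fit$x_saliences[, 1:2]))$r.squared
    expect_gt(r2, 0.95)
  }
})

test_that("first PLS component agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(132)
  n <- 80
  F2 <- matrix(rnorm(n * 2), n, 2)
  X <- F2 %*% matrix(rnorm(2 * 12), 2, 12) +
    matrix(rnorm(n * 12, sd = 0.7), n, 12)
  Y <- F2 %*% matrix(rnorm(2 * 9), 2, 9) +
    matrix(rnorm(n * 9, sd = 0.7), n, 9)
  fit <- pls_fit(X, Y, n_comp = 2)
  mo <- mixOmics::pls(X, Y, ncomp = 2, mode = "canonical")
  expect_gt(abs(cor(fit$x_saliences[, 1], mo$loadings$X[, 1])), 0.99)
  expect_gt(abs(cor(fit$y_saliences[, 1], mo$loadings$Y[, 1])), 0.99)
})

test_that("training-sample score correlations overfit under the null", {
  set.seed(128)
  r1 <- replicate(30, {
    X <- matrix(rnorm(100 * 30), 100, 30)
    Y <- matrix(rnorm(100 * 29), 100, 29)
    pls_fit(X, Y)$score_correlations[1L]
  })
  expect_gt(min(r1), 0.3)   # far above the true (zero) coupling
})

test_that("permutation p-values hit the attainable bound for real effects", {
  set.seed(129)
  n <- 80
  f <- rnorm(n)
  X <- outer(f, rep(1, 10)) + matrix(rnorm(n * 10, sd = 0.3), n, 10)
  Y <- outer(f, rep(1, 8)) + matrix(rnorm(n * 8, sd = 0.3), n, 8)
  fit <- pls_permutation(X, Y, n_comp = 3, n_perm = 199, seed = 5)
  expect_equal(fit$perm_p[1L], 1 / 200)
  expect_warning(pls_permutation(X, Y, n_comp = 2, n_perm = 50, seed = 5),
                 "100")
})

test_that("correspondence reports identity and sign-flip invariance", {
  set.seed(130)
  X <- matrix(rnorm(60 * 12), 60, 12)
  Y <- matrix(rnorm(60 * 10), 60, 10)
  fit <- pls_fit(X, Y, n_comp = 3)
  cr <- correspondence(fit, fit)
  expect_equal(cr$r_x, rep(1, 3), tolerance = 1e-12)
  expect_equal(cr$r_y, rep(1, 3), tolerance = 1e-12)
  flipped <- fit
  flipped$x_saliences <- -fit$x_saliences
  flipped$y_saliences <- -fit$y_saliences
  cr2 <- correspondence(fit, flipped)
  expect_equal(cr2$r_x, rep(1, 3), tolerance = 1e-12)
  expect_true(all(cr2$flip == -1))
  fit2 <- pls_fit(Y, X, n_comp = 3)
  expect_error(correspondence(fit, fit2), "differ")
})

test_that("PCA correspondence finds shared factors and ignores noise", {
  set.seed(131)
  mkX <- function(n) {
    F3 <- matrix(rnorm(n * 3), n, 3)
    L <- matrix(c(rep(c(1, 0, 0), each = 6),
                  rep(c(0, 1, 0), each = 6),
                  rep(c(0, 0, 1), each = 6)), nrow = 3, byrow = TRUE)
    amps <- c(3, 2, 1.3)
    (F3 * rep(amps, each = n)) %*% L + matrix(rnorm(n * 18, sd = 0.4), n, 18)
  }
  pc <- pca_correspondence(mkX(500), mkX(500), n_comp = 3)
  expect_true(all(pc$r > 0.8))
  # independent isotropic noise: no correspondence on average
  null_r <- replicate(20, mean(pca_correspondence(
    matrix(rnorm(80 * 10), 80, 10),
    matrix(rnorm(80 * 10), 80, 10), n_comp = 3)$r))
  expect_lt(mean(null_r), 0.5)
})

test_that("replication thresholds follow the training hit count", {
  expect_equal(replication_thresholds(15)$reported, 0.0033)
  expect_equal(replication_thresholds(4)$reported, 0.0125)
  expect_equal(replication_thresholds(1)$reported, 0.05)
  expect_true(is.na(replication_thresholds(0)$threshold))
})
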