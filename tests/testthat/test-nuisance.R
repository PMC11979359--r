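test_that("noise pool selection keeps top-SD unexcluded series", {
  sds <- rep(1, 100); sds[37] <- 10
  expect_equal(build_noise_pool(sds), c(37L, which.max(sds[-37])))
  # top series excluded by label: next-ranked unlabeled series wins
  sds2 <- seq(100, 1, length.out = 100)
  labels <- rep("ok", 100); labels[1] <- "amygdala"
  sel <- build_noise_pool(sds2, labels, exclusion_labels = "amygdala")
  expect_equal(sel, c(2L, 3L))
  # brute-force sort oracle at n = 1000
  set.seed(41)
  sds3 <- runif(1000)
  oracle <- order(sds3, decreasing = TRUE)[1:20]
  expect_equal(sort(build_noise_pool(sds3)), sort(oracle))
  expect_error(build_noise_pool(runif(10)), "at least 50")
  expect_error(build_noise_pool(runif(60), labels = rep("x", 60),
                                exclusion_labels = "x"), "excluded")
})

test_that("gaussian noise pools yield no component spikes", {
  set.seed(42)
  pool <- matrix(rnorm(200 * 60), 200, 60)
  sp <- detect_spike_regressors(pool)
  expect_equal(length(sp$component_spikes), 0L)
  expect_equal(ncol(sp$spikes), 0L)
})

test_that("a planted excursion is isolated at exactly its |z|>3 points", {
  set.seed(43)
  n <- 150
  s <- rnorm(n) * 0.9
  s[75] <- 8                      # single large excursion
  pool <- outer(rep(1, n), runif(60, 0.8, 1.2)) * s +
    matrix(rnorm(n * 60, sd = 0.1), n, 60)
  sp <- detect_spike_regressors(pool)
  expect_gte(length(sp$component_spikes), 1L)
  comp <- sp$component_spikes[[1L]]
  expect_true(comp[75] != 0)
  # nonzero entries all have |z| > 3 in the source component
  pc1 <- prcomp(scale(pool), center = FALSE)$x[, 1L]
  z <- as.numeric(scale(pc1))
  expect_true(all(abs(z[comp != 0]) > 3))
})

test_that("detrended FWD above 1 mm flags a motion spike frame", {
  set.seed(44)
  n <- 200
  fwd <- rgamma(n - 1, 2, scale = 0.05)
  fwd[120] <- 1.4
  pool <- matrix(rnorm(n * 60), n, 60)
  sp <- detect_spike_regressors(pool, fwd)
  expect_true(121L %in% sp$motion_spike_frames)  # leading zero pad shifts by 1
  expect_gte(ncol(sp$spikes), 1L)
})

test_that("CompCor recovers a planted orthogonal basis", {
  set.seed(45)
  n <- 400
  t0 <- seq_len(n)
  basis <- vapply(1:7, function(k) sin(2 * pi * k * t0 / n), numeric(n))
  # each pool series carries exactly one sinusoid; cluster sizes differ
  # so the PCA order is determined
  assign <- rep(1:7, times = c(12, 11, 10, 9, 8, 6, 4))
  pool <- basis[, assign] + matrix(rnorm(n * 60, sd = 0.01), n, 60)
  cc <- compcor_components(pool)
  expect_equal(ncol(cc), 14L)
  comps <- cc[, 1:7]
  # every planted sinusoid is captured by some component
  cors <- abs(cor(basis, comps))
  expect_true(all(apply(cors, 1L, max) > 0.99))
  # components mutually orthogonal
  cc_cor <- cor(comps)
  expect_lt(max(abs(cc_cor[upper.tri(cc_cor)])), 1e-8)
  expect_error(compcor_components(matrix(1, 100, 10)), "constant")
  expect_error(compcor_components(cbind(rnorm(100),
                                        matrix(0.5, 100, 9)) + 0), "rank|constant")
})

test_that("motion regressor pipeline builds 42 series and 7 orthogonal PCs", {
  set.seed(46)
  n <- 300
  s0 <- sin(2 * pi * seq_len(n) / 40)
  params <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  # a coherent oscillation driving all three translations (nodding)
  params[, 1:3] <- params[, 1:3] + outer(s0, c(0.6, 0.4, 0.5))
  fwd <- rgamma(n - 1, 2, scale = 0.1)
  mr <- motion_regressors(params, fwd)
  expect_equal(attr(mr, "design_width"), 42L)
  expect_equal(ncol(mr), 7L)
  cc <- cor(mr)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  # the retained PCs capture the planted oscillation almost entirely
  expect_gt(summary(lm(s0 ~ mr))$r.squared, 0.9)
  expect_error(motion_regressors(matrix(0, n, 6), rep(0, n)), "constant")
})

test_that("nuisance regression residuals are orthogonal to the design", {
  set.seed(47)
  n <- 250
  pool <- matrix(rnorm(n * 60), n, 60)
  cc <- compcor_components(pool)
  params <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  mr <- motion_regressors(params, rgamma(n - 1, 2, scale = 0.1))
  model <- nuisance_model(compcor_regressors = cc, motion_regressors = mr)
  Y <- matrix(rnorm(n * 10), n, 10)
  Yc <- regress_nuisance(Y, model)
  expect_lt(max(abs(cor(Yc, cbind(cc, mr)))), 1e-8)
  # data equal to a regressor column vanishes
  Y2 <- cbind(cc[, 1L], cc[, 1L])
  expect_lt(max(abs(regress_nuisance(Y2, model))), 1e-8)
  # planted task effect is removed when the design is supplied
  design <- matrix(rnorm(n * 2), n, 2)
  Y3 <- Y + design %*% matrix(5, 2, 10)
  model3 <- nuisance_model(compcor_regressors = cc,
                           motion_regressors = mr, task_design = design)
  Y3c <- regress_nuisance(Y3, model3)
  expect_lt(max(abs(cor(Y3c, design))), 1e-8)
})

test_that("data orthogonal to the design passes through unchanged", {
  set.seed(48)
  n <- 128
  reg <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(rnorm(n * 5), n, 5)
  # orthogonalize Y against regressors and intercept by construction
  Q <- qr.Q(qr(cbind(1, reg)))
  Yo <- Y - Q %*% crossprod(Q, Y)
  model <- nuisance_model(compcor_regressors = reg)
  expect_lt(max(abs(regress_nuisance(Yo, model) - Yo)), 1e-8)
})

test_that("spike regressors are zero off-spike and rank-reduced jointly", {
  set.seed(49)
  n <- 150
  s1 <- rnorm(n) * 0.8; s1[40] <- 7
  s2 <- rnorm(n) * 0.8; s2[90] <- -7
  pool <- cbind(outer(rep(1, n), runif(30, 0.9, 1.1)) * s1,
                outer(rep(1, n), runif(30, 0.9, 1.1)) * s2) +
    matrix(rnorm(n * 60, sd = 0.05), n, 60)
  sp <- detect_spike_regressors(pool)
  for (cs in sp$component_spikes) {
    src_z <- abs(as.numeric(scale(cs)))
    expect_true(all(cs[src_z <= .Machine$double.eps] == 0))
  }
  expect_true(sp$pca_reduced || ncol(sp$spikes) <= 1L)
})

test_that("cleaning removes a planted pool artifact from regional data", {
  sp <- tiny_spec(seed = 50L, artifact_strength = 4)
  co <- generate_cohort(sp)
  s <- 1L; q <- 1L
  res <- clean_sequence(co$bold[[s]][[q]], co$noise_pool[[s]][[q]],
                        co$motion[[s]][[q]], tr_seconds = sp$tr_seconds)
  art <- co$latents[[s]][[q]]$artifact
  # artifact share of regional variance before vs after cleaning
  share <- function(X) {
    mean(vapply(seq_len(ncol(X)), function(r) {
      f <- lm.fit(cbind(1, art), X[, r])
      1 - sum(f$residuals^2) / sum((X[, r] - mean(X[, r]))^2)
    }, numeric(1)))
  }
  before <- share(co$bold[[s]][[q]])
  after <- share(res$cleaned)
  expect_gt(before, 0.05)
  expect_lt(after, 0.1 * before)
})
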