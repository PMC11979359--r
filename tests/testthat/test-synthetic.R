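test_that("spec validation rejects impossible cohorts", {
  expect_error(cohort_spec(sequence_lengths = c(32L, 330L)), ">= 64")
  expect_error(cohort_spec(n_regions = 2L), "n_regions")
  expect_error(cohort_spec(tr_seconds = 0), "tr_seconds")
  expect_error(cohort_spec(group_lowfreq_scale = -1), "positive")
  expect_warning(cohort_spec(behavior_loadings = matrix(1, 26, 2)),
                 "rank deficient")
})

test_that("generation is bit-identical under a seed and differs across seeds", {
  sp <- tiny_spec(seed = 21L)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$bold, b$bold)
  expect_identical(a$motion, b$motion)
  expect_identical(a$behavior, b$behavior)
  c2 <- generate_cohort(tiny_spec(seed = 22L))
  expect_false(identical(a$bold[[1]][[1]], c2$bold[[1]][[1]]))
})

test_that("default sequence lengths give 1824 time points per subject", {
  sp <- cohort_spec(n_per_group = 1L, n_regions = 8L, seed = 23L)
  b <- generate_regional_bold(sp)
  expect_equal(sum(vapply(b[[1L]], nrow, integer(1))), 1824L)
  expect_equal(vapply(b[[1L]], nrow, integer(1)),
               c(330L, 330L, 240L, 240L, 504L, 180L))
  expect_false(anyNA(unlist(b)))
})

test_that("planted low-frequency group scaling is recoverable from latents", {
  sp <- cohort_spec(n_per_group = 4L, n_regions = 12L,
                    sequence_lengths = rep(330L, 2L),
                    group_lowfreq_scale = 1.5, subject_amp_sd = 0,
                    mode_amp_sd = 0,
                    order_variance_slope = 0, order_meancorr_slope = 0,
                    seed = 24L)
  co <- generate_cohort(sp)
  v <- vapply(seq_len(8L), function(s) {
    sig <- latent_component(co, s, 1L, "lowfreq")
    median(wavelet_variance(modwt(sig, 6L, warn_boundary = FALSE),
                            scales = 5L)[1L, ])
  }, numeric(1))
  ratio <- median(v[5:8]) / median(v[1:4])
  expect_equal(ratio, 1.5^2, tolerance = 0.15)
})

test_that("no planted effect leaves group variance ratios near 1", {
  sp <- cohort_spec(n_per_group = 6L, n_regions = 10L,
                    sequence_lengths = rep(256L, 2L),
                    group_lowfreq_scale = 1, subject_amp_sd = 0,
                    order_variance_slope = 0, seed = 25L)
  b <- generate_regional_bold(sp)
  g <- attr(b, "group")
  mv <- vapply(seq_along(b), function(s)
    mean(vapply(b[[s]], function(X)
      median(wavelet_variance(modwt(X, 6L, warn_boundary = FALSE),
                              scales = 5L)[1L, ]), numeric(1))),
    numeric(1))
  ratio <- median(mv[g == 1L]) / median(mv[g == 0L])
  expect_lt(abs(log(ratio)), log(1.25))
})

test_that("behavior table has the full battery and factor structure", {
  sp <- tiny_spec(seed = 26L)
  beh <- generate_behavior(sp)
  expect_equal(ncol(behavior_matrix(beh)), 29L)
  expect_equal(unname(colMeans(behavior_matrix(beh)[, 1:26])),
               rep(0, 26), tolerance = 1e-10)
  # single noiseless factor: all scales perfectly correlated
  sp1 <- cohort_spec(n_per_group = 20L, n_latent_factors = 1L,
                     behavior_noise_sd = 0, seed = 27L)
  b1 <- generate_behavior(sp1)
  cc <- cor(behavior_matrix(b1)[, 1:26])
  expect_equal(min(abs(cc)), 1, tolerance = 1e-10)
  # two orthogonal factors at large n: correlation close to closed form
  L <- cbind(c(rep(0.9, 13), rep(0, 13)), c(rep(0, 13), rep(0.9, 13)))
  L <- rbind(L, matrix(0, 0, 2))
  sp2 <- cohort_spec(n_per_group = 2500L, behavior_loadings = L,
                     behavior_noise_sd = 0.5, seed = 28L)
  b2 <- generate_behavior(sp2)
  emp <- cor(as.matrix(b2[, sprintf("scale_%02d", 1:26)]))
  pop_cov <- L %*% t(L) + diag(0.5^2, 26)
  pop <- stats::cov2cor(pop_cov)
  expect_lt(max(abs(emp - pop)), 0.05)
})

test_that("FWD traces are nonnegative with a controllable spike process", {
  sp <- tiny_spec(seed = 29L, spike_rate = 0, fwd_gamma_scale = 0.05,
                  subject_motion_sd = 0)
  mo <- generate_fwd_series(sp)
  fwd_all <- unlist(lapply(mo, function(s) lapply(s, `[[`, "fwd")))
  expect_true(all(fwd_all >= 0))
  expect_lt(max(fwd_all), 1)
  expect_equal(length(mo[[1L]][[1L]]$fwd),
               sp$sequence_lengths[1L] - 1L)
  sp2 <- tiny_spec(seed = 29L, spike_rate = 0.05)
  mo2 <- generate_fwd_series(sp2)
  fwd2 <- unlist(lapply(mo2, function(s) lapply(s, `[[`, "fwd")))
  expect_gt(max(fwd2), 1)
})

test_that("gamma marginal parameters are recoverable by MLE", {
  set.seed(30)
  x <- rgamma(1800, shape = 2, scale = 0.1)
  fit <- gswave:::.gamma_mle(x)
  expect_equal(fit$shape, 2, tolerance = 0.1)
  expect_equal(fit$scale, 0.1, tolerance = 0.1)
})

test_that("null motion ratio effect is non-significant in most replicates", {
  reps <- 60L
  p <- vapply(seq_len(reps), function(i) {
    sp <- cohort_spec(n_per_group = 8L, n_regions = 4L,
                      sequence_lengths = c(128L, 128L),
                      hf_motion_ratio_effect = 0, seed = 3000L + i)
    mo <- generate_fwd_series(sp)
    g <- attr(mo, "group")
    lr <- vapply(mo, function(s)
      mean(vapply(s, function(q) fwd_metrics(q$fwd)["hf_lf_ratio_log"],
                  numeric(1))), numeric(1))
    stats::t.test(lr ~ g)$p.value
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.90)
})

test_that("motion ratio effect moves the estimator monotonically", {
  lr_at <- function(effect, seed) {
    sp <- cohort_spec(n_per_group = 10L, n_regions = 4L,
                      sequence_lengths = c(256L, 256L),
                      hf_motion_ratio_effect = effect, seed = seed)
    mo <- generate_fwd_series(sp)
    g <- attr(mo, "group")
    lr <- vapply(mo, function(s)
      mean(vapply(s, function(q) fwd_metrics(q$fwd)["hf_lf_ratio_log"],
                  numeric(1))), numeric(1))
    mean(lr[g == 1L]) - mean(lr[g == 0L])
  }
  d <- vapply(c(0, 0.5, 1), function(e)
    mean(vapply(1:6, function(i) lr_at(e, 400L + i), numeric(1))),
    numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("fractional Brownian motion simulator has exact increments", {
  set.seed(31)
  for (H in c(0.3, 0.7)) {
    y <- simulate_fbm(8192, H)
    for (k in c(1L, 4L, 16L))
      expect_equal(var(diff(y, lag = k)) / k^(2 * H), 1, tolerance = 0.1)
  }
})
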