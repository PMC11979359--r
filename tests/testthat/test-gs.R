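test_that("global series arithmetic behaves as specified", {
  set.seed(81)
  x <- rnorm(200)
  X <- cbind(x, x, x)
  expect_equal(gs_timeseries(X), x)
  # opposite-sign regions cancel
  expect_equal(gs_timeseries(cbind(x, -x)), rep(0, 200))
  # weighted mode equalizes contributions of rescaled regions
  Y <- cbind(a = x + rnorm(200, sd = 0.3),
             b = 10 * (x + rnorm(200, sd = 0.3)))
  g <- gs_timeseries(Y, weighted = TRUE)
  expect_equal(abs(cor(g, scale(Y[, 1]))), abs(cor(g, scale(Y[, 2]))),
               tolerance = 1e-6)
  expect_warning(gs_timeseries(cbind(x, rep(1, 200)), weighted = TRUE),
                 "zero-variance")
})

test_that("tSNR is mean over SD and scale free", {
  x <- rnorm(500, mean = 100, sd = 10)
  expect_equal(tsnr(x), mean(x) / sd(x))
  expect_equal(tsnr(3 * x), tsnr(x))
  expect_error(tsnr(rep(5, 100)), "zero")
})

test_that("linear order contrast uses centered unit-spacing weights", {
  expect_equal(linear_order_contrast(0:5), 17.5)
  expect_equal(linear_order_contrast(rep(4, 6)), 0)
  expect_equal(linear_order_contrast(0:5, "first_positive"), -17.5)
  # first weight magnitude is 2.5 for six sequences
  e1 <- c(1, 0, 0, 0, 0, 0)
  expect_equal(abs(linear_order_contrast(e1)), 2.5)
  # five-sequence (task-only) restriction keeps unit spacing
  expect_equal(linear_order_contrast(0:4), 10)
  expect_error(linear_order_contrast(c(1, NA, 3, 4, 5, 6)), "missing")
})

test_that("GS table has 18 aggregated measures with correct transforms", {
  set.seed(82)
  data <- lapply(1:6, function(s)
    lapply(1:3, function(q) matrix(rnorm(128 * 8), 128, 8)))
  tab <- compute_gs_table(data, mode = "raw")
  expect_equal(dim(tab$aggregated), c(6L, 18L))
  expect_equal(unname(colMeans(tab$aggregated)), rep(0, 18),
               tolerance = 1e-10)
  expect_equal(unname(apply(tab$aggregated, 2, sd)), rep(1, 18),
               tolerance = 1e-10)
  # scaling one subject's data: variance metrics scale by s^2 pre-log,
  # mean correlation is unchanged
  data2 <- data
  data2[[1L]] <- lapply(data2[[1L]], function(X) 3 * X)
  tab2 <- compute_gs_table(data2, mode = "raw")
  expect_equal(tab2$per_sequence[1L, , 2L, ],
               9 * tab$per_sequence[1L, , 2L, ], tolerance = 1e-10)
  expect_equal(tab2$per_sequence[1L, , 1L, ],
               tab$per_sequence[1L, , 1L, ], tolerance = 1e-10)
  expect_error(compute_gs_table(list(data[[1]], data[[2]][1:2]),
                                mode = "raw"), "missing sequences")
})

test_that("standard GSR lowers mean correlation when a global mode is planted", {
  sp <- tiny_spec(seed = 83L, gs_strength = 1.5)
  co <- generate_cohort(sp)
  raw <- compute_gs_table(co$bold, mode = "raw")
  gsr <- compute_gs_table(co$bold, mode = "standard_gsr")
  # per subject, averaged over scales and sequences
  for (s in seq_along(co$bold)) {
    expect_lt(mean(gsr$per_sequence[s, , 1L, ]),
              mean(raw$per_sequence[s, , 1L, ]))
  }
})

test_that("cleaning removes a planted artifact's share of GS variance", {
  sp <- tiny_spec(seed = 84L, artifact_strength = 3)
  co <- generate_cohort(sp)
  s <- 1L; q <- 1L
  X <- co$bold[[s]][[q]]
  art <- co$latents[[s]][[q]]$artifact
  res <- clean_sequence(X, co$noise_pool[[s]][[q]], co$motion[[s]][[q]],
                        tr_seconds = sp$tr_seconds)
  g_raw <- gs_timeseries(X)             # pre-nuisance global series
  g_clean <- gs_timeseries(res$cleaned) # post-correction global series
  # absolute artifact variance carried by each global series
  art_var <- function(g) summary(lm(g ~ art))$r.squared * var(g)
  expect_gt(art_var(g_raw) / var(g_raw), 0.15)
  expect_lt(art_var(g_clean), 0.1 * art_var(g_raw))
})

test_that("group regression applies the study's correction arithmetic", {
  set.seed(85)
  n <- 60
  Y <- matrix(rnorm(n * 18), n, 18)
  colnames(Y) <- paste0("m", 1:18)
  g <- rep(0:1, each = 30)
  Y[, 1] <- Y[, 1] + g * 2          # one strong planted effect
  cov5 <- matrix(rnorm(n * 5), n, 5)
  res <- gs_group_regression(Y, g, cov5)
  expect_equal(attr(res, "alpha_reported"), 0.0009)
  expect_equal(attr(res, "n_tests"), 54L)
  expect_true(res$significant[1L])
  expect_equal(replication_thresholds(7)$reported, 0.0071)
  # null familywise error at the corrected threshold
  fwe <- mean(replicate(120, {
    Yn <- matrix(rnorm(40 * 18), 40, 18)
    gn <- rep(0:1, each = 20)
    any(gs_group_regression(Yn, gn)$significant)
  }))
  expect_lte(fwe, 0.05)
})

test_that("order contrasts recover a planted variance drift", {
  sp <- tiny_spec(seed = 86L, order_variance_slope = 0.2,
                  n_per_group = 6L)
  co <- generate_cohort(sp)
  tab <- compute_gs_table(co$bold, mode = "raw")
  ctr <- gs_order_contrasts(tab)
  # median-variance contrasts (columns 7..12) positive on average
  medvar_cols <- grep("median_regional_variance", colnames(ctr))
  expect_gt(mean(ctr[, medvar_cols]), 0)
  tt <- t.test(rowMeans(ctr[, medvar_cols]))
  expect_lt(tt$p.value, 0.01)
})

test_that("planted group effect strength moves group differences monotonically", {
  diffs <- vapply(c(1, 1.3, 1.6), function(gl) {
    sp <- cohort_spec(n_per_group = 6L, n_regions = 10L,
                      sequence_lengths = rep(192L, 3L),
                      group_lowfreq_scale = gl, subject_amp_sd = 0.1,
                      seed = 87L)
    co <- generate_cohort(sp)
    tab <- compute_gs_table(co$bold, mode = "raw")
    mv <- rowMeans(tab$aggregated[, grep("median_regional_variance_s5",
                                         colnames(tab$aggregated)),
                                  drop = FALSE])
    mean(mv[co$group == 1L]) - mean(mv[co$group == 0L])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})
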