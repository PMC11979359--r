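#' Bonferroni threshold
#'
#' `alpha / n_tests`, reported to four decimal places alongside full
#' precision (0.05 over 54 tests reports as 0.0009, over 18 as 0.0028).
#'
#' @param alpha base level.
#' @param n_tests number of tests (>= 1).
#' @return list with `threshold` and `reported`.
#' @export
bonferroni <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  thr <- alpha / n_tests
  list(threshold = thr, reported = round(thr, 4))
}

#' Nuisance-clean every sequence of a cohort
#'
#' Runs the two-stage spike/CompCor/motion pipeline on each
#' subject/sequence, and records the pre-nuisance global series used by
#' the raw-mode GS variance metric.
#'
#' @param cohort a `gs_cohort`.
#' @return object of class `clean_cohort`: list with `cleaned` (subject
#'   -> sequence -> matrix), `raw_global`, `motion_pca`
#'   (a `motion_components`), `cohort`.
#' @export
prepare_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "gs_cohort"))
  n_subj <- length(cohort$bold)
  cleaned <- vector("list", n_subj)
  raw_global <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    n_seq <- length(cohort$bold[[s]])
    cl <- vector("list", n_seq); rg <- vector("list", n_seq)
    for (q in seq_len(n_seq)) {
      res <- clean_sequence(cohort$bold[[s]][[q]],
                            cohort$noise_pool[[s]][[q]],
                            cohort$motion[[s]][[q]],
                            tr_seconds = cohort$spec$tr_seconds)
      cl[[q]] <- res$cleaned
      rg[[q]] <- gs_timeseries(cohort$bold[[s]][[q]])
    }
    cleaned[[s]] <- cl; raw_global[[s]] <- rg
  }
  mp <- cohort_motion_pca(cohort_fwd_metrics(cohort$motion), k = 5L)
  structure(list(cleaned = cleaned, raw_global = raw_global,
                 motion_pca = mp, cohort = cohort),
            class = "clean_cohort")
}

#' Experiment configuration
#'
#' @param train_spec,test_spec [cohort_spec()]s for the two cohorts
#'   (seeds must differ).
#' @param mode GS table mode.
#' @param selection_methods selection methods run for the brain/behavior
#'   analyses.
#' @param fc_scales wavelet scales for FC/variance measures.
#' @param n_perm PLS permutations.
#' @param n_comp PLS components.
#' @param alpha base significance level.
#' @param seed analysis-stage RNG seed (permutations).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(train_spec, test_spec,
                              mode = "raw",
                              selection_methods = c("correlation", "icc"),
                              fc_scales = 3:5,
                              n_perm = 500L, n_comp = 10L,
                              alpha = 0.05, seed = 1L) {
  stopifnot(inherits(train_spec, "cohort_spec"),
            inherits(test_spec, "cohort_spec"))
  if (train_spec$seed == test_spec$seed)
    stop("train and test specs must use different seeds")
  structure(list(train_spec = train_spec, test_spec = test_spec,
                 mode = mode, selection_methods = selection_methods,
                 fc_scales = fc_scales, n_perm = as.integer(n_perm),
                 n_comp = as.integer(n_comp), alpha = alpha,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# All per-cohort computations needed by the experiment report.
.analyse_cohort <- function(spec, config, tag) {
  cohort <- generate_cohort(spec)
  prep <- prepare_cohort(cohort)
  gs <- compute_gs_table(prep$cleaned, prep$raw_global, mode = config$mode)
  mot5 <- prep$motion_pca$scores
  group <- cohort$group
  gs_sex <- gs_group_regression(gs$aggregated, group, mot5,
                                alpha = config$alpha)
  contrasts <- gs_order_contrasts(gs)
  # contrasts stay uncentered: the intercept is the order effect itself
  order_test <- .intercept_test(contrasts, mot5)
  order_thr <- bonferroni(config$alpha, ncol(contrasts))
  order_test$significant <- order_test$p < order_thr$threshold
  meas <- fc_measure_set(prep$cleaned, scales = config$fc_scales)
  behavior <- behavior_matrix(cohort$behavior)
  scales_only <- behavior[, sprintf("scale_%02d", 1:26)]
  list(tag = tag, cohort = cohort, prep = prep, gs = gs,
       gs_sex = gs_sex, order_test = order_test, order_thr = order_thr,
       measures = meas, behavior = behavior, scales_only = scales_only,
       group = group, motion5 = mot5)
}

# Intercept (one-sample) test per column, adjusting for covariates.
.intercept_test <- function(Y, covariates = NULL) {
  Y <- as.matrix(Y)
  res <- lapply(seq_len(ncol(Y)), function(k) {
    fit <- if (is.null(covariates)) stats::lm(Y[, k] ~ 1)
           else stats::lm(Y[, k] ~ as.matrix(covariates))
    cf <- summary(fit)$coefficients
    c(estimate = cf[1L, 1L], t = cf[1L, 3L], p = cf[1L, 4L])
  })
  out <- as.data.frame(do.call(rbind, res))
  out$measure <- colnames(Y) %||% paste0("m", seq_len(ncol(Y)))
  out[, c("measure", "estimate", "t", "p")]
}

# Stack the per-scale FC (or variance) arrays of an fc_measures object
# into one subjects x sequences x measures candidate array.
.stack_measures <- function(meas, class = c("fc", "variance")) {
  class <- match.arg(class)
  lst <- if (class == "fc") meas$fc else meas$variance
  along3 <- function(a, b) {
    d <- dim(a); db <- dim(b)
    out <- array(NA_real_, c(d[1L], d[2L], d[3L] + db[3L]))
    out[, , seq_len(d[3L])] <- a
    out[, , d[3L] + seq_len(db[3L])] <- b
    out
  }
  Reduce(along3, lst)
}

#' Run the full train/test experiment
#'
#' Generates both cohorts, cleans them, computes GS metric tables with
#' group regressions (H1), linear order contrasts (H2), eigenvalue
#' power-law group comparisons (H1 post hoc), brain/behavior PLS over
#' the configured selection methods for FC and variance measures
#' (H3a/H3b) with testing-stage thresholds derived from training hits,
#' and motion/behavior checks (E1).  Selections are made on the training
#' cohort and frozen before application to the testing cohort.
#'
#' @param config an [experiment_config()].
#' @return object of class `experiment_report` (nested list; see the
#'   methods vignette for the schema).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  tr <- .analyse_cohort(config$train_spec, config, "train")
  te <- .analyse_cohort(config$test_spec, config, "test")

  # H1: demographic (group) effects on GS measures, train -> test
  n_train_hits <- sum(tr$gs_sex$significant)
  test_thr <- replication_thresholds(n_train_hits, config$alpha)
  h1 <- list(
    training = tr$gs_sex, testing = te$gs_sex,
    training_alpha = attr(tr$gs_sex, "alpha_corrected"),
    n_training_hits = n_train_hits,
    testing_alpha = test_thr$threshold,
    replicated = if (n_train_hits > 0)
      sum(te$gs_sex$p[tr$gs_sex$significant] < test_thr$threshold)
      else 0L,
    effect_profile_r = stats::cor(tr$gs_sex$t, te$gs_sex$t))

  # H1 post hoc: eigenvalue scaling -- scaled/unscaled x broadband/low
  eig <- list()
  for (sc in c(FALSE, TRUE)) {
    for (band in c("all", "low")) {
      ftr <- eigen_fit_table(tr$prep$cleaned, scaled = sc, band = band)
      fte <- eigen_fit_table(te$prep$cleaned, scaled = sc, band = band)
      eig[[paste0(if (sc) "scaled" else "unscaled", "_", band)]] <-
        list(scaled = sc, band = band,
             train = compare_eigen_params(ftr, tr$group, tr$motion5),
             test = compare_eigen_params(fte, te$group, te$motion5),
             r2 = c(train = mean(ftr$r_squared),
                    test = mean(fte$r_squared)))
    }
  }

  # H2: linear order effects
  h2 <- list(training = tr$order_test, testing = te$order_test,
             training_alpha = tr$order_thr$threshold,
             order_profile_r = stats::cor(tr$order_test$t, te$order_test$t))

  # H3: brain/behavior PLS per measure class and selection method
  h3 <- list()
  for (class in c("fc", "variance")) {
    cand_tr <- .stack_measures(tr$measures, class)
    cand_te <- .stack_measures(te$measures, class)
    per_method <- list()
    for (method in config$selection_methods) {
      sel <- select_features(cand_tr, tr$scales_only, method = method)
      pls_tr <- pls_permutation(sel$values, tr$behavior,
                                n_comp = config$n_comp,
                                n_perm = config$n_perm,
                                seed = config$seed)
      vals_te <- apply_selection(sel, cand_te)
      pls_te <- pls_permutation(vals_te, te$behavior,
                                n_comp = config$n_comp,
                                n_perm = config$n_perm,
                                seed = config$seed + 1L)
      per_method[[method]] <- list(selection = sel, train = pls_tr,
                                   test = pls_te,
                                   correspondence = correspondence(pls_tr,
                                                                   pls_te))
    }
    n_sig_train <- sum(vapply(per_method, function(m)
      sum(m$train$perm_p < config$alpha), numeric(1)))
    thr <- replication_thresholds(n_sig_train, config$alpha)
    replicated <- any(vapply(per_method, function(m)
      any(!is.na(thr$threshold) & m$test$perm_p < thr$threshold),
      logical(1)))
    h3[[class]] <- list(methods = per_method,
                        n_training_significant = n_sig_train,
                        testing_alpha = thr$threshold,
                        replicated = replicated)
  }

  # E1: motion vs behavior (PLS) and per-component group tests
  e1_pls <- pls_permutation(tr$prep$motion_pca$scores, tr$behavior,
                            n_comp = 5L, n_perm = config$n_perm,
                            seed = config$seed + 2L)
  e1_group <- lapply(list(train = tr, test = te), function(co) {
    sapply(seq_len(ncol(co$prep$motion_pca$scores)), function(j) {
      stats::t.test(co$prep$motion_pca$scores[, j] ~ co$group)$p.value
    })
  })
  motion_loading_r <- diag(stats::cor(tr$prep$motion_pca$loadings,
                                      te$prep$motion_pca$loadings))

  structure(list(config = config, h1 = h1, eigen = eig, h2 = h2,
                 h3 = h3,
                 e1 = list(pls = e1_pls, group_p = e1_group,
                           loading_correspondence = motion_loading_r),
                 train = tr[c("gs", "order_test")],
                 test = te[c("gs", "order_test")]),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report\n")
  cat("  H1 training hits:", x$h1$n_training_hits,
      "at alpha =", signif(x$h1$training_alpha, 3),
      "| replicated:", x$h1$replicated, "\n")
  cat("  H1 train/test effect profile r:",
      round(x$h1$effect_profile_r, 2), "\n")
  cat("  H2 training hits:", sum(x$h2$training$p < x$h2$training_alpha),
      "\n")
  for (cl in names(x$h3))
    cat("  H3", cl, "training-significant components:",
        x$h3[[cl]]$n_training_significant,
        "| replicated:", x$h3[[cl]]$replicated, "\n")
  cat("  Motion loading correspondence:",
      paste(round(x$e1$loading_correspondence, 2), collapse = " "), "\n")
  invisible(x)
}
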