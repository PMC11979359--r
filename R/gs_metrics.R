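#' Global signal time series of a regional matrix
#'
#' Unweighted mode averages the regional series as-is; weighted mode
#' z-transforms every region first so low-amplitude regions contribute
#' equally.  Zero-variance regions are dropped (with a warning) in
#' weighted mode.
#'
#' @param data time x region matrix.
#' @param weighted logical.
#' @return numeric global series.
#' @export
gs_timeseries <- function(data, weighted = FALSE) {
  X <- as.matrix(data)
  if (!weighted) return(rowMeans(X))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance region(s)")
    X <- X[, sds > 0, drop = FALSE]
  }
  rowMeans(scale(X))
}

#' Temporal signal-to-noise ratio
#'
#' Mean of a (raw, pre-nuisance) global series divided by its standard
#' deviation.
#'
#' @param x numeric series.
#' @return scalar tSNR.
#' @export
tsnr <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("zero standard deviation: tSNR undefined")
  mean(x) / s
}

#' Centered linear acquisition-order contrast
#'
#' Dot product of per-sequence values with centered, unit-spacing
#' weights.  For six sequences the weights are (-2.5, -1.5, ..., +2.5)
#' under the default `"increase_positive"` convention (a value rising
#' across the session gives a positive contrast); `"first_positive"`
#' flips the sign, weighting the first sequence by +2.5.
#'
#' @param values numeric vector of per-sequence values (length >= 2).
#' @param sign_convention `"increase_positive"` or `"first_positive"`.
#' @return scalar contrast.
#' @export
linear_order_contrast <- function(values,
                                  sign_convention = c("increase_positive",
                                                      "first_positive")) {
  sign_convention <- match.arg(sign_convention)
  if (anyNA(values)) stop("missing per-sequence values")
  k <- length(values)
  if (k < 2L) stop("need at least two sequences")
  w <- seq_len(k) - (k + 1) / 2
  if (sign_convention == "first_positive") w <- -w
  sum(w * values)
}

# The three GS summary metrics of one regional matrix at the six scales.
# `gs_series` is the series whose wavelet variance defines the
# gs_ts_variance metric (its provenance depends on the mode).
.gs_metrics_one <- function(X, gs_series, scales = 1:6,
                            meancorr_on = c("z", "r")) {
  meancorr_on <- match.arg(meancorr_on)
  d <- modwt(X, max(scales), warn_boundary = FALSE)
  dg <- modwt(gs_series, max(scales), warn_boundary = FALSE)
  wv <- wavelet_variance(d, scales = scales)
  gv <- wavelet_variance(dg, scales = scales)[, 1L]
  mc <- vapply(scales, function(s) {
    R <- wavelet_cor_matrix(d, s, fisher = (meancorr_on == "z"))
    mean(R[upper.tri(R)])
  }, numeric(1))
  list(mean_correlation = mc,
       median_regional_variance = apply(wv, 1L, stats::median),
       gs_ts_variance = gv)
}

#' GS summary metric table for a cohort
#'
#' Computes, per subject x sequence x wavelet scale, the three GS summary
#' metrics -- mean correlation across all region pairs (averaged on the
#' Fisher-z scale), median regional wavelet variance, and the wavelet
#' variance of the global time series -- in one of three modes:
#'
#' * `"raw"`: metrics on the nuisance-cleaned matrices; the GS variance
#'   metric uses the pre-nuisance global series (normalized data before
#'   correction) when supplied;
#' * `"standard_gsr"`: the unweighted global series of the cleaned data
#'   is regressed out of every region first and supplies the GS variance;
#' * `"weighted_gsr"`: as standard, with the per-region z-transformed
#'   (weighted) global series.
#'
#' The aggregated form averages each metric across sequences, log
#' transforms the two variance metrics, and z-scores the resulting
#' 3 x 6 = 18 columns across subjects.
#'
#' @param data list per subject of lists per sequence of cleaned
#'   time x region matrices.
#' @param raw_global optional list per subject of lists per sequence of
#'   pre-nuisance global series (used by `"raw"` mode GS variance).
#' @param mode one of `"raw"`, `"standard_gsr"`, `"weighted_gsr"`.
#' @param scales wavelet scales (default 1:6).
#' @return object of class `gs_metric_table`: list with `per_sequence`
#'   (subjects x sequences x 3 metrics x scales array), `aggregated`
#'   (subjects x 18 z-scored matrix), `mode`.
#' @export
compute_gs_table <- function(data, raw_global = NULL,
                             mode = c("raw", "standard_gsr", "weighted_gsr"),
                             scales = 1:6) {
  mode <- match.arg(mode)
  n_subj <- length(data)
  n_seq <- length(data[[1L]])
  metrics <- c("mean_correlation", "median_regional_variance",
               "gs_ts_variance")
  arr <- array(NA_real_, c(n_subj, n_seq, 3L, length(scales)),
               dimnames = list(NULL, NULL, metrics,
                               paste0("scale", scales)))
  for (s in seq_len(n_subj)) {
    if (length(data[[s]]) != n_seq)
      stop("subject ", s, " is missing sequences")
    for (q in seq_len(n_seq)) {
      X <- data[[s]][[q]]
      if (mode == "raw") {
        gs <- if (!is.null(raw_global)) raw_global[[s]][[q]]
              else gs_timeseries(X)
        Xa <- X
      } else {
        g <- gs_timeseries(X, weighted = (mode == "weighted_gsr"))
        Xa <- .residualize(X, g, "GS regressor")
        gs <- g
      }
      m <- .gs_metrics_one(Xa, gs, scales)
      arr[s, q, 1L, ] <- m$mean_correlation
      arr[s, q, 2L, ] <- m$median_regional_variance
      arr[s, q, 3L, ] <- m$gs_ts_variance
    }
  }
  seq_mean <- apply(arr, c(1L, 3L, 4L), mean)
  agg <- matrix(NA_real_, n_subj, 3L * length(scales))
  cn <- character(3L * length(scales))
  k <- 0L
  for (m in seq_len(3L)) {
    for (j in seq_along(scales)) {
      k <- k + 1L
      v <- seq_mean[, m, j]
      if (m >= 2L) v <- log(v)   # the two variance metrics
      agg[, k] <- v
      cn[k] <- paste0(metrics[m], "_s", scales[j])
    }
  }
  agg <- scale(agg)
  colnames(agg) <- cn
  structure(list(per_sequence = arr, aggregated = agg, mode = mode,
                 scales = scales),
            class = "gs_metric_table")
}

#' @export
print.gs_metric_table <- function(x, ...) {
  cat("GS metric table (", x$mode, "): ", nrow(x$aggregated),
      " subjects x ", ncol(x$aggregated), " measures\n", sep = "")
  invisible(x)
}

#' Per-subject linear order contrasts of GS metrics
#'
#' Applies [linear_order_contrast()] to the untransformed per-sequence
#' values of every metric x scale.
#'
#' @param table a `gs_metric_table`.
#' @param sign_convention see [linear_order_contrast()].
#' @return subjects x 18 matrix of contrast values.
#' @export
gs_order_contrasts <- function(table,
                               sign_convention = "increase_positive") {
  arr <- table$per_sequence
  n_subj <- dim(arr)[1L]
  out <- matrix(NA_real_, n_subj, dim(arr)[3L] * dim(arr)[4L])
  cn <- character(ncol(out))
  k <- 0L
  for (m in seq_len(dim(arr)[3L])) {
    for (j in seq_len(dim(arr)[4L])) {
      k <- k + 1L
      out[, k] <- apply(arr[, , m, j, drop = FALSE], 1L, function(v)
        linear_order_contrast(as.numeric(v), sign_convention))
      cn[k] <- paste0(dimnames(arr)[[3L]][m], "_",
                      dimnames(arr)[[4L]][j], "_order")
    }
  }
  colnames(out) <- cn
  out
}

#' Covariate-adjusted group regression on GS measures
#'
#' Regresses each measure on a predictor (e.g. the binary group) plus
#' motion covariates, and applies the training-stage Bonferroni
#' threshold `alpha / (n_measures * n_demographics)`.  The testing-stage
#' threshold for a replication cohort is `alpha / n_training_hits`.
#'
#' @param measures subjects x measures matrix (e.g. the `aggregated`
#'   element of a `gs_metric_table`, or order contrasts).
#' @param predictor numeric/binary vector.
#' @param covariates optional subjects x k matrix (motion PC scores).
#' @param alpha base level (default 0.05).
#' @param n_demographics how many predictors share the correction family
#'   (default 3: sex, age, education).
#' @return data frame with per-measure `estimate`, `t`, `p`,
#'   `significant` at the corrected threshold; attributes
#'   `alpha_corrected`, `n_tests`.
#' @export
gs_group_regression <- function(measures, predictor, covariates = NULL,
                                alpha = 0.05, n_demographics = 3L) {
  Y <- as.matrix(measures)
  stopifnot(length(predictor) == nrow(Y))
  X <- cbind(predictor = predictor)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    q <- qr(cbind(1, predictor, covariates))
    if (q$rank < 2L + ncol(covariates)) {
      warning("dropping collinear covariate column(s)")
      keep <- q$pivot[seq_len(q$rank)]
      keep <- keep[keep > 2L] - 2L
      covariates <- covariates[, keep, drop = FALSE]
    }
    X <- cbind(X, covariates)
  }
  n_tests <- ncol(Y) * n_demographics
  thr <- bonferroni(alpha, n_tests)
  res <- lapply(seq_len(ncol(Y)), function(k) {
    fit <- stats::lm(Y[, k] ~ X)
    cf <- summary(fit)$coefficients
    c(estimate = cf[2L, 1L], t = cf[2L, 3L], p = cf[2L, 4L])
  })
  out <- as.data.frame(do.call(rbind, res))
  out$measure <- colnames(Y) %||% paste0("m", seq_len(ncol(Y)))
  out$significant <- out$p < thr$threshold
  out <- out[, c("measure", "estimate", "t", "p", "significant")]
  attr(out, "alpha_corrected") <- thr$threshold
  attr(out, "alpha_reported") <- thr$reported
  attr(out, "n_tests") <- n_tests
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
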