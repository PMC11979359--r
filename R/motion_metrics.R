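# Variance of a zero-sum FIR filter applied to fBm:
# E[(c * B)^2] = -1/2 sum_ij c_i c_j |i - j|^(2H).
.fbm_filter_var <- function(coefs, H) {
  idx <- seq_along(coefs) - 1L
  D <- abs(outer(idx, idx, "-"))^(2 * H)
  -0.5 * drop(coefs %*% D %*% coefs)
}

# Combined filter: level-1 MODWT smoothing followed by a lag-k second
# difference, expressed as coefficients on the raw series.
.smooth_diff_filter <- function(k) {
  g <- la8_filters()$g
  len <- 2L * k + length(g)
  c1 <- numeric(len); c2 <- numeric(len); c3 <- numeric(len)
  c1[seq_along(g)] <- g                      # x_{t}
  c2[k + seq_along(g)] <- g                  # x_{t+k}
  c3[2L * k + seq_along(g)] <- g             # x_{t+2k}
  c3 - 2 * c2 + c1
}

# Invert the exact expected log2 variance ratio (lag 4 over lag 2) of the
# smoothed second difference under fBm; monotone in H.
.invert_smooth_ratio <- function(observed) {
  c2 <- .smooth_diff_filter(2L)
  c4 <- .smooth_diff_filter(4L)
  f <- function(H) log2(.fbm_filter_var(c4, H) / .fbm_filter_var(c2, H)) -
    observed
  lo <- f(0.01); hi <- f(0.99)
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    return(if (observed > 0) 0.99 else 0.01)
  stats::uniroot(f, c(0.01, 0.99))$root
}

# Gamma MLE via the profile likelihood in the shape parameter:
# solves log(shape) - digamma(shape) = log(mean(x)) - mean(log(x)).
.gamma_mle <- function(x) {
  if (any(x <= 0)) {
    mp <- min(x[x > 0]) / 2
    x[x <= 0] <- mp
  }
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) stop("degenerate sample for gamma fit")
  f <- function(a) log(a) - digamma(a) - s
  shape <- stats::uniroot(f, c(1e-3, 1e6))$root
  list(shape = shape, scale = mean(x) / shape)
}

#' Hurst exponent estimates for fractional Brownian motion
#'
#' Three estimators:
#' 1. `h1`: discrete second-derivative variance-ratio estimator,
#'    `H = log2(V2 / V1) / 2` with `V1` the mean squared second difference
#'    at unit lag and `V2` at doubled lag;
#' 2. `h2`: the same variance-ratio principle applied to a low-pass
#'    (level-1 MODWT smooth) version of the series with lags 2 and 4;
#'    because the smoothing filter distorts the raw `2^(2H)` ratio, the
#'    estimate is obtained by inverting the exact expected log-ratio
#'    under fractional Brownian motion (computed in closed form from the
#'    fBm covariance of the combined smooth-and-difference filter);
#' 3. `h3`: log-regression of per-scale wavelet detail variance on scale
#'    index: for fBm the scale-`j` MODWT variance grows as `2^(2 H j)`,
#'    so `H = slope / 2` from a regression of `log2` variance on `j`
#'    over scales 2..J (scale 1 sits at the Nyquist edge where the
#'    octave-band approximation is poorest and is excluded).
#'
#' @param x numeric series (length >= 128).
#' @param n_levels scales used by the wavelet regression estimator.
#' @return named numeric vector `c(h1, h2, h3)`.
#' @export
hurst_estimates <- function(x, n_levels = 5L) {
  x <- as.numeric(x)
  if (length(x) < 64L) stop("need at least 64 points")
  if (stats::sd(x) == 0) stop("constant series has no Hurst exponent")
  n <- length(x)
  tiny <- 1e-12 * stats::var(x)
  d1 <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]
  d2 <- x[seq(5, n)] - 2 * x[seq(3, n - 2)] + x[seq(1, n - 4)]
  boundary <- FALSE
  if (mean(d1^2) <= tiny) {           # locally smooth (e.g. a ramp):
    h1 <- 1; boundary <- TRUE         # maximal persistence
  } else h1 <- 0.5 * log2(mean(d2^2) / mean(d1^2))
  flt <- la8_filters()
  xe <- c(x, rev(x))
  sm <- .modwt_step(matrix(xe, ncol = 1), flt$g, 1L)[seq_len(n), 1L]
  m <- length(sm)
  i1 <- seq_len(m - 4L)
  s1 <- sm[i1 + 4L] - 2 * sm[i1 + 2L] + sm[i1]
  i2 <- seq_len(m - 8L)
  s2 <- sm[i2 + 8L] - 2 * sm[i2 + 4L] + sm[i2]
  # drop the reflection seam, where the smoothed ramp bends
  trim1 <- i1 > 8L & i1 < m - 16L
  trim2 <- i2 > 8L & i2 < m - 16L
  if (mean(s1[trim1]^2) <= tiny) {
    h2 <- 1; boundary <- TRUE
  } else h2 <- .invert_smooth_ratio(log2(mean(s2[trim2]^2) /
                                           mean(s1[trim1]^2)))
  J <- min(n_levels, floor(log2(n)) - 2L)
  wv <- wavelet_variance(modwt(x, J, warn_boundary = FALSE),
                         scales = seq_len(J))[, 1L]
  if (all(wv <= tiny)) {
    h3 <- 1; boundary <- TRUE
  } else {
    j <- 2:J
    fit <- stats::lm(log2(wv[j]) ~ j)
    h3 <- unname(stats::coef(fit)[2L]) / 2
  }
  structure(c(h1 = h1, h2 = h2, h3 = h3), boundary = boundary)
}

#' The 12 framewise-displacement motion metrics
#'
#' Summary fingerprint of one FWD trace: `max_fwd_log` (log maximum),
#' `mean_fwd`, `median_fwd`, `sd_fwd`, `skew_fwd` (bias-corrected by
#' default), `midfreq_ratio` (wavelet variance at scales 3-5 over total),
#' `hf_lf_ratio_log` (log of scales 1-2 over scale 6 wavelet variance),
#' `gamma_shape_A` and `gamma_scale_B_log` from a maximum-likelihood
#' gamma fit, and three Hurst estimates (`hurst_1..3`) of the cumulated
#' trace.
#'
#' @param fwd nonnegative FWD series, length >= 64.
#' @param skew_type skewness convention passed to [e1071::skewness()]
#'   (2 = bias-corrected, the default).
#' @return named numeric vector of length 12.
#' @export
fwd_metrics <- function(fwd, skew_type = 2L) {
  fwd <- as.numeric(fwd)
  if (length(fwd) < 64L) stop("need at least 64 FWD values")
  if (any(fwd < 0)) stop("FWD must be nonnegative")
  if (stats::sd(fwd) == 0)
    stop("constant FWD series: skewness and Hurst metrics are undefined")
  J <- min(6L, floor(log2(length(fwd))) - 1L)
  wv <- wavelet_variance(modwt(fwd, J, warn_boundary = FALSE),
                         scales = seq_len(J))[, 1L]
  total <- sum(wv)
  mid <- sum(wv[intersect(3:5, seq_len(J))]) / total
  hf <- sum(wv[intersect(1:2, seq_len(J))])
  lf <- unname(wv[min(6L, J)])
  gam <- .gamma_mle(fwd)
  hu <- hurst_estimates(cumsum(fwd - mean(fwd)))
  c(max_fwd_log = log(max(fwd)),
    mean_fwd = mean(fwd),
    median_fwd = stats::median(fwd),
    sd_fwd = stats::sd(fwd),
    skew_fwd = e1071::skewness(fwd, type = skew_type),
    midfreq_ratio = mid,
    hf_lf_ratio_log = log(hf / lf),
    gamma_shape_A = gam$shape,
    gamma_scale_B_log = log(gam$scale),
    hurst_1 = unname(hu["h1"]),
    hurst_2 = unname(hu["h2"]),
    hurst_3 = unname(hu["h3"]))
}

#' Motion metrics for every subject and sequence of a cohort
#'
#' @param motion list as returned by [generate_fwd_series()] (or the
#'   `motion` element of a `gs_cohort`).
#' @return array subjects x sequences x 12.
#' @export
cohort_fwd_metrics <- function(motion) {
  n_subj <- length(motion)
  n_seq <- length(motion[[1L]])
  out <- array(NA_real_, c(n_subj, n_seq, 12L),
               dimnames = list(NULL, NULL, names(fwd_metrics(motion[[1L]][[1L]]$fwd))))
  for (s in seq_len(n_subj))
    for (q in seq_len(n_seq))
      out[s, q, ] <- fwd_metrics(motion[[s]][[q]]$fwd)
  out
}

#' Cohort-level PCA of motion metrics
#'
#' Averages each of the 12 metrics across the six sequences, z-scores the
#' means, and extracts `k` principal components.  The sign convention
#' makes each component's largest-magnitude loading positive so loading
#' tables are reproducible.
#'
#' @param metrics subjects x sequences x 12 array from
#'   [cohort_fwd_metrics()], or a subjects x 12 matrix of means.
#' @param k components retained (default 5).
#' @return object of class `motion_components`: list with `scores`
#'   (subjects x k), `loadings` (12 x k, unit norm),
#'   `eigenvalue_fractions`, and `metric_means`.
#' @export
cohort_motion_pca <- function(metrics, k = 5L) {
  M <- if (length(dim(metrics)) == 3L) apply(metrics, c(1L, 3L), mean)
       else as.matrix(metrics)
  if (anyNA(M))
    stop("missing metrics for subject(s): ",
         paste(which(rowSums(is.na(M)) > 0), collapse = ", "))
  if (nrow(M) < ncol(M)) stop("need at least ", ncol(M), " subjects")
  Z <- scale(M)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(load) <- colnames(scores) <- sprintf("C%d", seq_len(k))
  structure(list(scores = scores, loadings = load,
                 eigenvalue_fractions = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 metric_means = M),
            class = "motion_components")
}

#' @export
print.motion_components <- function(x, ...) {
  cat("Motion PCA:", ncol(x$scores), "components;",
      "eigenvalue fractions:",
      paste(sprintf("%.2f", x$eigenvalue_fractions), collapse = " "), "\n")
  invisible(x)
}
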