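#' Discrete-cosine high-pass filter
#'
#' Projects out the low-frequency discrete cosine basis up to the cutoff
#' period (default 128 s), the convention used by GLM-based fMRI
#' analyses.
#'
#' @param x numeric vector or time x series matrix.
#' @param tr_seconds sampling interval (s).
#' @param cutoff_seconds high-pass cutoff period (s).
#' @return filtered series, same shape.
#' @export
dct_highpass <- function(x, tr_seconds, cutoff_seconds = 128) {
  X <- as.matrix(x)
  n <- nrow(X)
  K <- floor(2 * n * tr_seconds / cutoff_seconds)
  if (K < 1L) return(if (is.matrix(x)) X else drop(X))
  t0 <- seq_len(n) - 0.5
  C <- vapply(seq_len(K), function(k) cos(pi * k * t0 / n), numeric(n))
  out <- .residualize(X, C, "DCT basis")
  if (is.matrix(x)) out else drop(out)
}

#' Association of one region with the global signal
#'
#' Both series are high-pass filtered (128-s discrete cosine basis),
#' then the region is regressed on the GS (with intercept); the slope
#' t statistic is mapped to a z score through the normal quantile of the
#' t distribution function at the model's residual degrees of freedom.
#' |z| is capped at `z_cap` (near-perfect fits are flagged).
#'
#' @param region,gs numeric series of equal length.
#' @param tr_seconds sampling interval (s).
#' @param highpass_seconds cutoff period (default 128 s).
#' @param z_cap cap on |z| (default 8).
#' @return list with `z`, `t`, `df`, `capped`.
#' @export
region_gs_association <- function(region, gs, tr_seconds = 1.5,
                                  highpass_seconds = 128, z_cap = 8) {
  stopifnot(length(region) == length(gs))
  if (stats::sd(region) == 0 || stats::sd(gs) == 0)
    stop("zero-variance input")
  r <- dct_highpass(region, tr_seconds, highpass_seconds)
  g <- dct_highpass(gs, tr_seconds, highpass_seconds)
  n <- length(r)
  K <- floor(2 * n * tr_seconds / highpass_seconds)
  df <- n - 2L - K
  rho <- stats::cor(r, g)
  t <- rho * sqrt(df / (1 - rho^2))
  if (!is.finite(t)) t <- sign(rho) * Inf
  lp <- stats::pt(-abs(t), df, log.p = TRUE)
  z <- -sign(t) * stats::qnorm(lp, log.p = TRUE)
  capped <- abs(z) > z_cap || !is.finite(z)
  if (capped) z <- sign(t) * z_cap
  list(z = z, t = t, df = df, capped = capped)
}

#' Per-region GS topography maps for a cohort
#'
#' @param data list per subject of lists per sequence of time x region
#'   matrices (typically nuisance-cleaned).
#' @param gs_mode `"standard"` (unweighted GS) or `"weighted"`.
#' @param tr_seconds,highpass_seconds see [region_gs_association()].
#' @return array subjects x sequences x regions of z statistics.
#' @export
topography_maps <- function(data, gs_mode = c("standard", "weighted"),
                            tr_seconds = 1.5, highpass_seconds = 128) {
  gs_mode <- match.arg(gs_mode)
  n_subj <- length(data)
  n_seq <- length(data[[1L]])
  P <- ncol(data[[1L]][[1L]])
  out <- array(NA_real_, c(n_subj, n_seq, P))
  for (s in seq_len(n_subj)) {
    for (q in seq_len(n_seq)) {
      X <- data[[s]][[q]]
      g <- gs_timeseries(X, weighted = (gs_mode == "weighted"))
      Xf <- dct_highpass(X, tr_seconds, highpass_seconds)
      gf <- dct_highpass(g, tr_seconds, highpass_seconds)
      n <- nrow(Xf)
      K <- floor(2 * n * tr_seconds / highpass_seconds)
      df <- n - 2L - K
      rho <- suppressWarnings(stats::cor(Xf, gf))
      rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
      tt <- rho * sqrt(df / (1 - rho^2))
      lp <- stats::pt(-abs(tt), df, log.p = TRUE)
      z <- -sign(tt) * stats::qnorm(lp, log.p = TRUE)
      z[!is.finite(z)] <- sign(tt[!is.finite(z)]) * 8
      out[s, q, ] <- pmin(pmax(z, -8), 8)
    }
  }
  dimnames(out)[[3L]] <- colnames(data[[1L]][[1L]])
  out
}

# Fast per-column two-group regression t statistics of Y on x (both
# already residualized on covariates), for permutation loops.
.col_tstats <- function(Y, x) {
  n <- nrow(Y)
  x <- x - mean(x)
  sx2 <- sum(x^2)
  b <- drop(crossprod(Y, x)) / sx2
  Yc <- sweep(Y, 2L, colMeans(Y))
  rss <- colSums(Yc^2) - b^2 * sx2
  se <- sqrt(pmax(rss, 0) / (n - 2L) / sx2)
  tt <- b / se
  tt[se == 0] <- 0
  tt
}

#' Group test on topography maps with max-statistic permutation
#'
#' Sequence-averaged z maps are residualized on covariates (as is the
#' group indicator), then per-region group t statistics are referred to
#' the permutation distribution of the maximum absolute statistic across
#' regions, controlling family-wise error at the parcel level.
#'
#' @param maps subjects x regions matrix (or subjects x sequences x
#'   regions array, averaged across sequences).
#' @param group binary vector.
#' @param covariates optional subjects x k matrix (age, education,
#'   motion PCs).
#' @param n_perm permutations (default 1000; < 100 warns).
#' @param alpha FWE level.
#' @param seed RNG seed for the permutation stream.
#' @return list with per-region `t`, `p_fwe`, `significant` indices,
#'   `max_stat_null`.
#' @export
group_topography_test <- function(maps, group, covariates = NULL,
                                  n_perm = 1000L, alpha = 0.05,
                                  seed = 1L) {
  if (length(dim(maps)) == 3L) maps <- apply(maps, c(1L, 3L), mean)
  Y <- as.matrix(maps)
  stopifnot(nrow(Y) == length(group))
  if (min(table(group)) < 2L) stop("need at least 2 subjects per group")
  if (n_perm < 100L) warning("fewer than 100 permutations")
  Yr <- .residualize(Y, covariates, "covariates")
  xr <- drop(.residualize(matrix(as.numeric(group), ncol = 1), covariates,
                          "covariates"))
  t_obs <- .col_tstats(Yr, xr)
  set.seed(seed)
  max_null <- replicate(n_perm, {
    max(abs(.col_tstats(Yr, sample(xr))))
  })
  p_fwe <- vapply(abs(t_obs), function(t0)
    (1 + sum(max_null >= t0)) / (n_perm + 1), numeric(1))
  list(t = t_obs, p_fwe = p_fwe,
       significant = which(p_fwe < alpha),
       max_stat_null = max_null)
}

#' Linear order trend on topography maps (sign-flip max-stat test)
#'
#' Computes the per-subject linear order contrast of each region's z map
#' across sequence positions, then a one-sample test per region with
#' sign-flipping permutation of subjects and max-|t| FWE correction.
#'
#' @param maps subjects x sequences x regions array.
#' @param n_perm sign-flip permutations.
#' @param alpha FWE level.
#' @param seed RNG seed.
#' @param sign_convention see [linear_order_contrast()].
#' @return list with per-region `contrast_mean`, `t`, `p_fwe`,
#'   `significant`.
#' @export
order_topography_trend <- function(maps, n_perm = 1000L, alpha = 0.05,
                                   seed = 1L,
                                   sign_convention = "increase_positive") {
  stopifnot(length(dim(maps)) == 3L)
  n_subj <- dim(maps)[1L]; n_seq <- dim(maps)[2L]
  w <- seq_len(n_seq) - (n_seq + 1) / 2
  if (sign_convention == "first_positive") w <- -w
  C <- apply(maps, c(1L, 3L), function(v) sum(w * v))
  one_sample_t <- function(M) {
    m <- colMeans(M); s <- apply(M, 2L, stats::sd)
    tt <- m / (s / sqrt(nrow(M)))
    tt[s == 0] <- 0
    tt
  }
  t_obs <- one_sample_t(C)
  set.seed(seed)
  max_null <- replicate(n_perm, {
    flips <- sample(c(-1, 1), n_subj, replace = TRUE)
    max(abs(one_sample_t(C * flips)))
  })
  p_fwe <- vapply(abs(t_obs), function(t0)
    (1 + sum(max_null >= t0)) / (n_perm + 1), numeric(1))
  list(contrast_mean = colMeans(C), t = t_obs, p_fwe = p_fwe,
       significant = which(p_fwe < alpha))
}
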