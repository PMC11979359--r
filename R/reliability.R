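#' Intra-class correlation ICC(3,1)
#'
#' Two-way mixed, consistency, single-measurement ICC across the
#' sequences (treated as fixed raters):
#' `ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS)` from the two-way ANOVA
#' mean squares.  `ICC(2,1)` (absolute agreement, random raters) is
#' available as an option.
#'
#' @param m subjects x sequences matrix without missing cells.
#' @param type `"ICC3,1"` (default) or `"ICC2,1"`.
#' @return scalar ICC; when between-subject variance is zero the result
#'   is nonpositive and carries attribute `degenerate = TRUE`.
#' @export
icc31 <- function(m, type = c("ICC3,1", "ICC2,1")) {
  type <- match.arg(type)
  M <- as.matrix(m)
  if (anyNA(M)) stop("missing cells")
  n <- nrow(M); k <- ncol(M)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 sequences")
  G <- mean(M)
  Ri <- rowMeans(M); Cj <- colMeans(M)
  SSB <- k * sum((Ri - G)^2)
  SSC <- n * sum((Cj - G)^2)
  SST <- sum((M - G)^2)
  SSE <- SST - SSB - SSC
  BMS <- SSB / (n - 1)
  JMS <- SSC / (k - 1)
  EMS <- SSE / ((n - 1) * (k - 1))
  out <- if (type == "ICC3,1") {
    (BMS - EMS) / (BMS + (k - 1) * EMS)
  } else {
    (BMS - EMS) / (BMS + (k - 1) * EMS + k * (JMS - EMS) / n)
  }
  if (BMS <= EMS) attr(out, "degenerate") <- TRUE
  out
}

# Vectorized ICC(3,1) across many measures: A is subjects x sequences x
# measures.  Same mean-squares arithmetic as icc31(), column-wise.
.icc31_array <- function(A) {
  stopifnot(length(dim(A)) == 3L)
  n <- dim(A)[1L]; k <- dim(A)[2L]; M <- dim(A)[3L]
  flat <- matrix(A, n * k, M)
  G <- colMeans(flat)
  Ri <- matrix(0, n, M)
  Cj <- matrix(0, k, M)
  for (j in seq_len(k)) Ri <- Ri + A[, j, ]
  Ri <- Ri / k
  for (i in seq_len(k)) Cj[i, ] <- colMeans(A[, i, ])
  SSB <- k * colSums((Ri - rep(G, each = n))^2)
  SSC <- n * colSums((Cj - rep(G, each = k))^2)
  SST <- colSums((flat - rep(G, each = n * k))^2)
  SSE <- SST - SSB - SSC
  BMS <- SSB / (n - 1)
  EMS <- SSE / ((n - 1) * (k - 1))
  (BMS - EMS) / (BMS + (k - 1) * EMS)
}

#' Per-sequence wavelet FC and variance measures for a cohort
#'
#' Builds the measure arrays used by the reliability and selection
#' analyses: per wavelet scale, the Fisher-z FC of every region pair and
#' the log wavelet variance of every region, for each subject and
#' sequence.
#'
#' @param data list per subject of lists per sequence of time x region
#'   matrices.
#' @param scales wavelet scales (default 3:5 for FC-class measures).
#' @return object of class `fc_measures`: list with `fc` (list per scale
#'   of subjects x sequences x pairs arrays of z values), `variance`
#'   (list per scale of subjects x sequences x regions arrays of log
#'   variances), `pair_index` (2-column matrix of region indices),
#'   `scales`.
#' @export
fc_measure_set <- function(data, scales = 3:5) {
  n_subj <- length(data)
  n_seq <- length(data[[1L]])
  P <- ncol(data[[1L]][[1L]])
  pairs <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  fc <- lapply(scales, function(s)
    array(NA_real_, c(n_subj, n_seq, nrow(pairs))))
  va <- lapply(scales, function(s) array(NA_real_, c(n_subj, n_seq, P)))
  names(fc) <- names(va) <- paste0("scale", scales)
  for (s in seq_len(n_subj)) {
    for (q in seq_len(n_seq)) {
      d <- modwt(data[[s]][[q]], max(scales), warn_boundary = FALSE)
      wv <- wavelet_variance(d, scales = scales)
      for (i in seq_along(scales)) {
        R <- wavelet_cor_matrix(d, scales[i], fisher = TRUE)
        fc[[i]][s, q, ] <- R[upper.tri(R)]
        va[[i]][s, q, ] <- log(wv[i, ])
      }
    }
  }
  structure(list(fc = fc, variance = va, pair_index = pairs,
                 scales = scales),
            class = "fc_measures")
}

#' ICC inventory over all FC and variance measures
#'
#' ICC(3,1) of every FC (per scale, per region pair) and variance (per
#' scale, per region) measure across the sequences, with summary
#' statistics and relative (z-scored) regional mean-ICC maps.
#'
#' @param measures an `fc_measures` object.
#' @return object of class `icc_table`: list with `fc_icc` / `var_icc`
#'   (lists per scale), `summary` (data frame: class, scale, n, mean,
#'   max, min, skewness, fraction above 0.6), and `regional_fc_icc_z` /
#'   `regional_var_icc_z` (region-level z-scored mean ICCs per scale).
#' @export
icc_inventory <- function(measures) {
  stopifnot(inherits(measures, "fc_measures"))
  pairs <- measures$pair_index
  P <- max(pairs)
  fc_icc <- lapply(measures$fc, .icc31_array)
  var_icc <- lapply(measures$variance, .icc31_array)
  summarize <- function(v, class, scale) data.frame(
    class = class, scale = scale, n = length(v),
    mean = mean(v), max = max(v), min = min(v),
    skewness = e1071::skewness(v, type = 2L),
    frac_above_0.6 = mean(v > 0.6))
  summ <- rbind(
    do.call(rbind, Map(summarize, fc_icc, "fc", measures$scales)),
    do.call(rbind, Map(summarize, var_icc, "variance", measures$scales)))
  rownames(summ) <- NULL
  region_mean_fc <- lapply(fc_icc, function(v) {
    acc <- numeric(P); cnt <- numeric(P)
    for (col in 1:2) {
      t1 <- tapply(v, pairs[, col], sum)
      acc[as.integer(names(t1))] <- acc[as.integer(names(t1))] + t1
      t2 <- tapply(rep(1, length(v)), pairs[, col], sum)
      cnt[as.integer(names(t2))] <- cnt[as.integer(names(t2))] + t2
    }
    as.numeric(scale(acc / cnt))
  })
  region_var <- lapply(var_icc, function(v) as.numeric(scale(v)))
  structure(list(fc_icc = fc_icc, var_icc = var_icc, summary = summ,
                 regional_fc_icc_z = region_mean_fc,
                 regional_var_icc_z = region_var),
            class = "icc_table")
}

#' @export
print.icc_table <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Cross-cohort ICC profile correlation
#'
#' Pearson correlation between the concatenated ICC profiles (all
#' measures of one class across scales) of two cohorts sharing a
#' generating specification.
#'
#' @param a,b `icc_table` objects with identical measure inventories.
#' @param class `"fc"` or `"variance"`.
#' @return scalar correlation.
#' @export
icc_profile_correlation <- function(a, b, class = c("fc", "variance")) {
  class <- match.arg(class)
  va <- if (class == "fc") unlist(a$fc_icc) else unlist(a$var_icc)
  vb <- if (class == "fc") unlist(b$fc_icc) else unlist(b$var_icc)
  if (length(va) != length(vb)) stop("measure inventories differ")
  stats::cor(va, vb)
}
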