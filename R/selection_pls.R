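#' Feature selection for brain/behavior PLS
#'
#' Implements the four selection methods over a candidate pool of brain
#' measures.  Measures with absolute skewness above `skew_max` are
#' excluded before ranking.  Ties are broken by measure id (stable
#' sort), so selections are deterministic.
#'
#' * `"correlation"`: largest maximum absolute correlation of the
#'   sequence-averaged measure with any behavior scale column;
#' * `"icc"`: largest ICC(3,1) across sequences;
#' * `"combined"`: largest sum of the z-scored ICC and z-scored maximum
#'   absolute correlation;
#' * `"dynamic"`: largest spread of per-sequence correlations -- for
#'   each measure, the maximum over behavior scales of (maximum minus
#'   minimum correlation across sequences); the selected feature's value
#'   is the measure's difference between its high- and low-correlation
#'   sequences.
#'
#' @param candidates subjects x sequences x measures array of
#'   per-sequence measure values.
#' @param behavior subjects x scales matrix (questionnaire scales only).
#' @param method selection method.
#' @param k number of measures to select (default 30).
#' @param iccs optional precomputed ICC vector (length = measures);
#'   computed from `candidates` when missing.
#' @param skew_max skewness exclusion threshold (default 1).
#' @return object of class `feature_selection`: list with `indices`,
#'   `method`, `skew_excluded`, `values` (subjects x k feature matrix
#'   to submit to PLS), and for the dynamic method `hi_seq`/`lo_seq`.
#' @export
select_features <- function(candidates, behavior,
                            method = c("correlation", "icc", "combined",
                                       "dynamic"),
                            k = 30L, iccs = NULL, skew_max = 1) {
  method <- match.arg(method)
  stopifnot(length(dim(candidates)) == 3L)
  B <- as.matrix(behavior)
  n <- dim(candidates)[1L]
  M <- dim(candidates)[3L]
  stopifnot(nrow(B) == n)
  mean_meas <- apply(candidates, c(1L, 3L), mean)
  skew <- apply(mean_meas, 2L, e1071::skewness, type = 2L)
  eligible <- which(abs(skew) <= skew_max & !is.na(skew))
  excluded <- setdiff(seq_len(M), eligible)
  if (length(eligible) == 0L) stop("no measures survive the skew filter")
  if (k > length(eligible)) {
    warning("pool smaller than k = ", k, "; retaining all ",
            length(eligible), " measures")
    k <- length(eligible)
  }
  need_icc <- method %in% c("icc", "combined")
  if (need_icc && is.null(iccs)) iccs <- .icc31_array(candidates)
  max_abs_cor <- function(Mm) {
    cc <- abs(stats::cor(Mm, B))
    apply(cc, 1L, max)
  }
  hi_seq <- lo_seq <- NULL
  score <- switch(method,
    correlation = max_abs_cor(mean_meas),
    icc = as.numeric(iccs),
    combined = {
      z1 <- as.numeric(scale(as.numeric(iccs)))
      z2 <- as.numeric(scale(max_abs_cor(mean_meas)))
      z1 + z2
    },
    dynamic = {
      n_seq <- dim(candidates)[2L]
      # per-sequence correlation of each measure with each scale
      cors <- array(NA_real_, c(n_seq, M, ncol(B)))
      for (q in seq_len(n_seq))
        cors[q, , ] <- stats::cor(candidates[, q, ], B)
      spread <- apply(cors, 2L, function(cm) max(apply(cm, 2L, max) -
                                                   apply(cm, 2L, min)))
      best_beh <- apply(cors, 2L, function(cm)
        which.max(apply(cm, 2L, max) - apply(cm, 2L, min)))
      hi_seq <- vapply(seq_len(M), function(m)
        which.max(cors[, m, best_beh[m]]), integer(1))
      lo_seq <- vapply(seq_len(M), function(m)
        which.min(cors[, m, best_beh[m]]), integer(1))
      spread
    })
  score_e <- score[eligible]
  sel <- eligible[order(-score_e, eligible)][seq_len(k)]
  values <- if (method == "dynamic") {
    V <- matrix(NA_real_, n, k)
    for (i in seq_along(sel)) {
      m <- sel[i]
      V[, i] <- candidates[, hi_seq[m], m] - candidates[, lo_seq[m], m]
    }
    V
  } else mean_meas[, sel, drop = FALSE]
  colnames(values) <- paste0("feat_", sel)
  structure(list(indices = sel, method = method, skew_excluded = excluded,
                 values = values,
                 hi_seq = if (!is.null(hi_seq)) hi_seq[sel],
                 lo_seq = if (!is.null(lo_seq)) lo_seq[sel]),
            class = "feature_selection")
}

#' Apply a frozen selection to a new cohort
#'
#' Recomputes the feature values for the indices selected on the
#' training cohort, without re-ranking.
#'
#' @param selection a `feature_selection` from the training cohort.
#' @param candidates test-cohort subjects x sequences x measures array.
#' @return subjects x k feature matrix.
#' @export
apply_selection <- function(selection, candidates) {
  stopifnot(inherits(selection, "feature_selection"))
  sel <- selection$indices
  if (selection$method == "dynamic") {
    V <- matrix(NA_real_, dim(candidates)[1L], length(sel))
    for (i in seq_along(sel))
      V[, i] <- candidates[, selection$hi_seq[i], sel[i]] -
        candidates[, selection$lo_seq[i], sel[i]]
    colnames(V) <- paste0("feat_", sel)
    V
  } else {
    out <- apply(candidates[, , sel, drop = FALSE], c(1L, 3L), mean)
    colnames(out) <- paste0("feat_", sel)
    out
  }
}

#' Symmetric PLS of brain and behavior matrices
#'
#' Singular value decomposition of the cross-covariance of the
#' column-standardized matrices.  Saliences are the singular vectors;
#' each component's X and Y scores are correlated, with signs aligned so
#' the correlation is nonnegative.
#'
#' @param X subjects x p brain matrix.
#' @param Y subjects x q behavior matrix.
#' @param n_comp components (default 10).
#' @return object of class `pls_result`: `x_saliences` (p x K),
#'   `y_saliences` (q x K), `x_scores`, `y_scores`,
#'   `score_correlations` (in `[0, 1]`), `singular_values`,
#'   `explained_x`, `explained_y`.
#' @export
pls_fit <- function(X, Y, n_comp = 10L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) <= n_comp) stop("need more subjects than components")
  const_x <- which(apply(X, 2L, stats::sd) == 0)
  const_y <- which(apply(Y, 2L, stats::sd) == 0)
  if (length(const_x) > 0)
    stop("constant X column(s): ",
         paste(colnames(X)[const_x] %||% const_x, collapse = ", "))
  if (length(const_y) > 0)
    stop("constant Y column(s): ",
         paste(colnames(Y)[const_y] %||% const_y, collapse = ", "))
  Xs <- scale(X); Ys <- scale(Y)
  C <- crossprod(Xs, Ys) / (nrow(Xs) - 1)
  K <- min(n_comp, nrow(C), ncol(C))
  sv <- svd(C, nu = K, nv = K)
  U <- sv$u; V <- sv$v
  xs <- Xs %*% U; ys <- Ys %*% V
  rc <- numeric(K)
  for (j in seq_len(K)) {
    r <- stats::cor(xs[, j], ys[, j])
    if (is.na(r)) r <- 0
    if (r < 0) { V[, j] <- -V[, j]; ys[, j] <- -ys[, j]; r <- -r }
    rc[j] <- r
  }
  structure(list(x_saliences = U, y_saliences = V,
                 x_scores = xs, y_scores = ys,
                 score_correlations = rc,
                 singular_values = sv$d[seq_len(K)],
                 explained_x = colMeans(stats::cor(Xs, xs)^2),
                 explained_y = colMeans(stats::cor(Ys, ys)^2),
                 n_comp = K),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("PLS:", x$n_comp, "components; score correlations:",
      paste(sprintf("%.2f", x$score_correlations), collapse = " "), "\n")
  if (!is.null(x$perm_p))
    cat("permutation p:",
        paste(sprintf("%.4f", x$perm_p), collapse = " "), "\n")
  invisible(x)
}

#' Permutation inference for PLS components
#'
#' Rows of Y are permuted `n_perm` times; each component's observed
#' score correlation is referred to the permutation distribution of the
#' same-rank correlation: `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param X,Y as in [pls_fit()].
#' @param n_comp components.
#' @param n_perm permutations (default 5000; < 100 warns).
#' @param seed RNG seed.
#' @return the `pls_result` with `perm_p` and `n_perm` added.
#' @export
pls_permutation <- function(X, Y, n_comp = 10L, n_perm = 5000L, seed = 1L) {
  if (n_perm < 100L) warning("fewer than 100 permutations")
  obs <- pls_fit(X, Y, n_comp)
  K <- obs$n_comp
  set.seed(seed)
  n <- nrow(as.matrix(Y))
  exceed <- numeric(K)
  Xs <- scale(as.matrix(X)); Ys <- scale(as.matrix(Y))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Yp <- Ys[idx, , drop = FALSE]
    C <- crossprod(Xs, Yp) / (n - 1)
    sv <- svd(C, nu = K, nv = K)
    xs <- Xs %*% sv$u; ys <- Yp %*% sv$v
    rp <- abs(vapply(seq_len(K), function(j)
      stats::cor(xs[, j], ys[, j]), numeric(1)))
    rp[is.na(rp)] <- 0
    exceed <- exceed + (rp >= obs$score_correlations)
  }
  obs$perm_p <- (1 + exceed) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}

# Sign-aligned correlation of two loading vectors.
.aligned_cor <- function(a, b) {
  r <- stats::cor(a, b)
  list(r = abs(r), sign = sign(r))
}

#' Train/test correspondence of PLS saliences
#'
#' Correlates each component's X and Y saliences between a training and
#' a testing fit, flipping the test component's joint sign to maximize
#' agreement (the flip is reported).  Offset-by-one correspondence and
#' explained-variance profiles are included.
#'
#' @param train,test `pls_result` objects over identical feature
#'   inventories.
#' @return data frame per component: `r_x`, `r_y` (sign-aligned),
#'   `flip`, `r_x_offset` (train k vs test k+1), `explained_x_train`,
#'   `explained_x_test`.
#' @export
correspondence <- function(train, test) {
  stopifnot(inherits(train, "pls_result"), inherits(test, "pls_result"))
  if (nrow(train$x_saliences) != nrow(test$x_saliences) ||
      nrow(train$y_saliences) != nrow(test$y_saliences))
    stop("feature inventories differ between cohorts")
  K <- min(train$n_comp, test$n_comp)
  rows <- lapply(seq_len(K), function(j) {
    rx <- stats::cor(train$x_saliences[, j], test$x_saliences[, j])
    ry <- stats::cor(train$y_saliences[, j], test$y_saliences[, j])
    flip <- if ((rx + ry) < 0) -1 else 1
    off <- if (j < test$n_comp)
      stats::cor(train$x_saliences[, j], test$x_saliences[, j + 1L])
      else NA_real_
    data.frame(component = j, r_x = flip * rx, r_y = flip * ry,
               flip = flip, r_x_offset = off,
               explained_x_train = train$explained_x[j],
               explained_x_test = test$explained_x[j])
  })
  do.call(rbind, rows)
}

#' Train/test correspondence of PCA loadings
#'
#' Proxy for factor stability: per-rank correlation (after sign
#' alignment) of PCA loadings across two cohorts, plus offset-by-one
#' correlations.
#'
#' @param X_train,X_test matrices with identical columns.
#' @param n_comp ranks compared.
#' @return data frame per rank: `r` (aligned), `r_offset`.
#' @export
pca_correspondence <- function(X_train, X_test, n_comp = 10L) {
  if (ncol(X_train) != ncol(X_test)) stop("differing feature sets")
  pa <- stats::prcomp(scale(X_train), center = FALSE)
  pb <- stats::prcomp(scale(X_test), center = FALSE)
  K <- min(n_comp, ncol(pa$rotation), ncol(pb$rotation))
  rows <- lapply(seq_len(K), function(j) {
    r <- abs(stats::cor(pa$rotation[, j], pb$rotation[, j]))
    off <- if (j < ncol(pb$rotation))
      abs(stats::cor(pa$rotation[, j], pb$rotation[, j + 1L]))
      else NA_real_
    data.frame(rank = j, r = r, r_offset = off)
  })
  do.call(rbind, rows)
}

#' Replication threshold from training-stage hits
#'
#' `alpha / n` rounded to four decimals for reporting, the correction
#' applied to a testing cohort given `n` significant training findings.
#'
#' @param n_training_significant count of training-stage findings.
#' @param alpha base level.
#' @return list with `threshold` (full precision), `reported` (4 dp);
#'   both `NA` when the count is zero (nothing to test).
#' @export
replication_thresholds <- function(n_training_significant, alpha = 0.05) {
  if (n_training_significant == 0L)
    return(list(threshold = NA_real_, reported = NA_real_))
  list(threshold = alpha / n_training_significant,
       reported = round(alpha / n_training_significant, 4))
}
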