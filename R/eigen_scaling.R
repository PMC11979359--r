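#' Eigenvalue spectrum of a time-by-region matrix
#'
#' PCA eigenvalues (principal-component variances).  In scaled mode every
#' region is z-transformed first, so the eigenvalues are those of the
#' regional correlation matrix and sum to the region count; constant
#' regions are dropped with a warning.
#'
#' @param data time x region matrix (>= 4 regions).
#' @param scaled z-transform regions before the PCA.
#' @return nonincreasing vector of nonnegative eigenvalues.
#' @export
eigen_spectrum <- function(data, scaled = FALSE) {
  X <- as.matrix(data)
  if (ncol(X) < 4L) stop("need at least 4 regions")
  if (scaled) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " constant region(s) in scaled mode")
      X <- X[, sds > 0, drop = FALSE]
    }
    X <- scale(X)
  }
  ev <- stats::prcomp(X, center = TRUE, scale. = FALSE)$sdev^2
  pmax(ev, 0)
}

#' Power-law fit to an eigenvalue spectrum
#'
#' Nonlinear least squares of `EVM = a * (#EV)^b + c` over eigenvalue
#' ranks `1..min(n, index_max)`, with multi-start initialization over
#' decay exponents `b0 = -0.5, -1, -2` (best residual sum of squares
#' wins; deterministic given the input).  `a` captures the amplitude
#' (scaling) of the spectrum, `b` its decay rate (complexity), `c` the
#' offset.
#'
#' @param eigenvalues numeric vector (>= 10 values).
#' @param index_max largest eigenvalue rank entering the fit
#'   (default 100).
#' @return object of class `eigen_fit`: list with `a`, `b`, `c`,
#'   `r_squared`, `n_fit`.
#' @export
fit_power_law <- function(eigenvalues, index_max = 100L) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 10L) stop("need at least 10 eigenvalues")
  n <- min(length(ev), index_max)
  ev <- ev[seq_len(n)]
  idx <- seq_len(n)
  df <- data.frame(i = idx, y = ev)
  best <- NULL
  for (b0 in c(-0.5, -1, -2)) {
    a0 <- max(ev[1L] - ev[n], 1e-6)
    c0 <- min(ev)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * i^b + c, data = df,
                        start = list(a = a0, b = b0, c = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("power-law fit failed to converge from all starts (n = ", n,
         ", range = [", signif(min(ev), 3), ", ", signif(max(ev), 3), "])")
  cf <- stats::coef(best$fit)
  sst <- sum((ev - mean(ev))^2)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]),
                 r_squared = 1 - best$rss / sst, n_fit = n),
            class = "eigen_fit")
}

#' @export
print.eigen_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: a = %.4g, b = %.4g, c = %.4g, R^2 = %.4f\n",
              x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

# Low-frequency filtered version of a regional matrix: the level-3 MODWT
# smooth, i.e. everything below the scale-3 band (scales 4-6 plus the
# final smooth).  Identical to summing detail series 4-6 and the smooth
# of a deeper decomposition, at a fraction of the cost.
.lowfreq_filter <- function(X) {
  d <- modwt(X, 3L, warn_boundary = FALSE)
  flt <- la8_filters()
  Ne <- nrow(d$V_ext)
  zero <- matrix(0, Ne, ncol(d$V_ext))
  S <- d$V_ext
  for (k in rev(seq_len(3L))) {
    S <- .imodwt_step(zero, S, flt$h, flt$g, 2L^(k - 1L))
  }
  S[seq_len(d$n), , drop = FALSE]
}

#' Power-law fits for every subject and sequence
#'
#' @param data list per subject of lists per sequence of time x region
#'   matrices.
#' @param scaled z-transform regions before PCA.
#' @param band `"all"` (broadband) or `"low"` (wavelet scales 4-6 plus
#'   smooth, filtered before the PCA).
#' @param index_max see [fit_power_law()].
#' @return data frame with subject, sequence, band, scaled, a, b, c,
#'   r_squared.
#' @export
eigen_fit_table <- function(data, scaled = FALSE,
                            band = c("all", "low"), index_max = 100L) {
  band <- match.arg(band)
  rows <- list()
  for (s in seq_along(data)) {
    for (q in seq_along(data[[s]])) {
      X <- data[[s]][[q]]
      if (band == "low") X <- .lowfreq_filter(X)
      f <- fit_power_law(eigen_spectrum(X, scaled = scaled), index_max)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, sequence = q, band = band, scaled = scaled,
        a = f$a, b = f$b, c = f$c, r_squared = f$r_squared)
    }
  }
  do.call(rbind, rows)
}

#' Group comparison of power-law parameters
#'
#' Averages each parameter across sequences per subject (log transform
#' for `a`, which is strictly positive for decaying spectra) and tests
#' the group effect with covariate-adjusted regression.
#'
#' @param fits data frame from [eigen_fit_table()].
#' @param group binary vector, one entry per subject.
#' @param covariates optional subject x k matrix.
#' @return data frame with one row per parameter (`log_a`, `b`, `c`):
#'   estimate, t, p.
#' @export
compare_eigen_params <- function(fits, group, covariates = NULL) {
  if (min(table(group)) < 3L) stop("each group needs at least 3 subjects")
  agg <- stats::aggregate(fits[, c("a", "b", "c")],
                          by = list(subject = fits$subject), FUN = mean)
  agg <- agg[order(agg$subject), ]
  stopifnot(nrow(agg) == length(group))
  par_mat <- cbind(log_a = log(pmax(agg$a, .Machine$double.eps)),
                   b = agg$b, c = agg$c)
  X <- cbind(group = group)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  res <- lapply(colnames(par_mat), function(p) {
    fit <- stats::lm(par_mat[, p] ~ X)
    cf <- summary(fit)$coefficients
    data.frame(parameter = p, estimate = cf[2L, 1L], t = cf[2L, 3L],
               p = cf[2L, 4L])
  })
  do.call(rbind, res)
}
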