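# Least-asymmetric 8-tap (la8 / sym4) scaling filter, unit-DWT normalisation.
# The MODWT filters are these divided by sqrt(2).
LA8_SCALING <- c(-0.075765714789273325, -0.029635527645998510,
                  0.497618667632015454,  0.803738751805916141,
                  0.297857795605277365, -0.099219543576847216,
                 -0.012603967262037833,  0.032223100604042702)

#' MODWT filters for the la8 wavelet
#'
#' Returns the scaling (`g`) and wavelet (`h`) filters used by the maximal
#' overlap discrete wavelet transform, already rescaled by `1/sqrt(2)`.
#' The wavelet filter is obtained from the scaling filter by the quadrature
#' mirror relationship `h[l] = (-1)^l g[L-1-l]` (zero-based `l`).
#'
#' @return A list with numeric vectors `g` and `h` of length 8.
#' @export
la8_filters <- function() {
  g <- LA8_SCALING
  L <- length(g)
  l <- seq_len(L) - 1L
  h <- (-1)^l * rev(g)
  list(g = g / sqrt(2), h = h / sqrt(2))
}

# One circular MODWT filtering step at level j (tau = 2^(j-1)) applied to all
# columns of V at once.  Index arithmetic follows the usual pyramid
# convention W[t] = sum_l f[l] * V[(t - tau*l) mod N].
.modwt_step <- function(V, f, tau) {
  N <- nrow(V)
  out <- matrix(0, N, ncol(V))
  t0 <- seq_len(N) - 1L
  for (l in seq_along(f)) {
    idx <- ((t0 - tau * (l - 1L)) %% N) + 1L
    out <- out + f[l] * V[idx, , drop = FALSE]
  }
  out
}

# Inverse step: reconstructs V_{j-1} from (W_j, V_j).
.imodwt_step <- function(W, V, h, g, tau) {
  N <- nrow(V)
  out <- matrix(0, N, ncol(V))
  t0 <- seq_len(N) - 1L
  for (l in seq_along(g)) {
    idx <- ((t0 + tau * (l - 1L)) %% N) + 1L
    out <- out + h[l] * W[idx, , drop = FALSE] + g[l] * V[idx, , drop = FALSE]
  }
  out
}

#' Filter width at a given MODWT level
#'
#' `L_j = (2^j - 1)(L - 1) + 1` for a base filter of width `L = 8`.
#' Coefficients with time index below `L_j` involve the boundary.
#'
#' @param level decomposition level (scale index), positive integer.
#' @return Integer filter width.
#' @export
modwt_filter_width <- function(level) {
  as.integer((2^as.integer(level) - 1) * 7 + 1)
}

#' Maximal overlap discrete wavelet transform
#'
#' Decomposes one series (or each column of a matrix) into `n_levels` wavelet
#' detail coefficient series plus a final smooth, using the la8 filter and
#' reflection boundary handling: the series is extended to length `2N` by
#' appending its reversal, a circular MODWT is applied, and the first `N`
#' coefficients are retained.  The MODWT is undecimated and shift covariant,
#' so every coefficient series has the length of the input.
#'
#' @param x numeric vector or time-by-series matrix.
#' @param n_levels number of decomposition levels (default 6).
#' @param warn_boundary warn when the series is shorter than the deepest
#'   filter width (all coefficients at that scale touch the boundary).
#' @return An object of class `modwt_decomp`: a list with
#'   * `W`: list of detail coefficient matrices, one per scale 1..`n_levels`;
#'   * `V`: final smooth coefficient matrix;
#'   * `n`: original series length;
#'   * `n_nonboundary`: per-scale count of boundary-free coefficients
#'     `max(N - L_j + 1, 0)`;
#'   * `wavelet`, `boundary`: tags.
#' @export
modwt <- function(x, n_levels = 6L, warn_boundary = TRUE) {
  X <- as.matrix(x)
  if (!is.numeric(X)) stop("`x` must be numeric")
  if (anyNA(X)) stop("`x` contains missing values")
  N <- nrow(X)
  n_levels <- as.integer(n_levels)
  if (N < 2L^n_levels)
    stop("series length ", N, " is shorter than 2^levels = ", 2L^n_levels)
  if (warn_boundary && N < modwt_filter_width(n_levels))
    warning("series length ", N, " is below the level-", n_levels,
            " filter width ", modwt_filter_width(n_levels),
            "; deepest scales have no boundary-free coefficients")
  flt <- la8_filters()
  # reflection extension
  Xe <- rbind(X, X[rev(seq_len(N)), , drop = FALSE])
  W <- vector("list", n_levels)
  Ve <- Xe
  for (j in seq_len(n_levels)) {
    tau <- 2L^(j - 1L)
    Wj <- .modwt_step(Ve, flt$h, tau)
    Ve <- .modwt_step(Ve, flt$g, tau)
    W[[j]] <- Wj
  }
  nb <- pmax(N - vapply(seq_len(n_levels), modwt_filter_width, integer(1)) + 1L, 0L)
  structure(list(
    W = lapply(W, function(w) w[seq_len(N), , drop = FALSE]),
    V = Ve[seq_len(N), , drop = FALSE],
    W_ext = W, V_ext = Ve,
    n = N, n_levels = n_levels,
    n_nonboundary = nb,
    wavelet = "la8", boundary = "reflection"
  ), class = "modwt_decomp")
}

#' Multiresolution analysis (additive decomposition)
#'
#' Inverts the MODWT one scale at a time to obtain detail series `D_j` and a
#' final smooth `S` that sum exactly to the input:
#' `x = D_1 + ... + D_J + S`.
#'
#' @param d a `modwt_decomp` object.
#' @return list with `D` (list of detail matrices) and `S` (smooth matrix),
#'   each truncated to the original series length.
#' @export
modwt_mra <- function(d) {
  stopifnot(inherits(d, "modwt_decomp"))
  flt <- la8_filters()
  J <- d$n_levels
  Ne <- nrow(d$V_ext)
  zero <- matrix(0, Ne, ncol(d$V_ext))
  D <- vector("list", J)
  for (j in seq_len(J)) {
    # push scale-j coefficients alone back to level 0
    Vj <- zero
    Wj <- d$W_ext[[j]]
    for (k in rev(seq_len(j))) {
      tau <- 2L^(k - 1L)
      Wk <- if (k == j) Wj else zero
      Vj <- .imodwt_step(Wk, Vj, flt$h, flt$g, tau)
    }
    D[[j]] <- Vj[seq_len(d$n), , drop = FALSE]
  }
  S <- d$V_ext
  for (k in rev(seq_len(J))) {
    tau <- 2L^(k - 1L)
    S <- .imodwt_step(zero, S, flt$h, flt$g, tau)
  }
  list(D = D, S = S[seq_len(d$n), , drop = FALSE])
}

#' Nominal frequency band of a wavelet scale
#'
#' Scale `j` of a dyadic wavelet decomposition spans
#' `[fN / 2^j, fN / 2^(j-1)]` where `fN = 1/(2 tr)` is the Nyquist
#' frequency.  At `tr = 1.5` s, scale 1 covers 0.17-0.33 Hz and scale 6
#' covers about 0.005-0.01 Hz.
#'
#' @param scale integer scale index, 1-6 in this package's analyses.
#' @param tr_seconds sampling interval in seconds.
#' @return list with `scale`, `f_low`, `f_high` (Hz).
#' @export
scale_frequency_band <- function(scale, tr_seconds) {
  stopifnot(length(scale) == 1L, scale >= 1, tr_seconds > 0)
  fN <- 1 / (2 * tr_seconds)
  list(scale = as.integer(scale),
       f_low = fN / 2^scale,
       f_high = fN / 2^(scale - 1))
}

# MODWT detail coefficients are heavily autocorrelated (the transform is
# undecimated), so the usable coefficient count badly overstates the
# information available to correlation and variance estimates.  The
# redundancy factor sum_k rho_j(k)^2 is computed once per level from the
# autocorrelation of the equivalent level-j wavelet filter; the
# effective sample size is (usable count) / redundancy.
.eq_df_env <- new.env(parent = emptyenv())
.modwt_redundancy <- function(level) {
  key <- as.character(level)
  if (!is.null(.eq_df_env[[key]])) return(.eq_df_env[[key]])
  flt <- la8_filters()
  conv_full <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
      out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
    out
  }
  upsample <- function(f, j) {
    if (j == 1L) return(f)
    out <- numeric((length(f) - 1L) * 2L^(j - 1L) + 1L)
    out[seq(1L, length(out), by = 2L^(j - 1L))] <- f
    out
  }
  g_casc <- 1
  if (level > 1L)
    for (j in seq_len(level - 1L))
      g_casc <- conv_full(g_casc, upsample(flt$g, j))
  hj <- conv_full(g_casc, upsample(flt$h, level))
  ac <- conv_full(hj, rev(hj))
  ac <- ac / max(ac)
  .eq_df_env[[key]] <- sum(ac^2)
  .eq_df_env[[key]]
}

# Internal: usable coefficients and effective df at a scale.  When enough
# boundary-free coefficients exist they are used ("interior"); otherwise
# all N reflection-boundary coefficients are used ("reflection").  The
# df in both cases is the usable count divided by the filter redundancy.
.scale_support <- function(d, scale, min_interior = 8L) {
  nb <- d$n_nonboundary[scale]
  if (nb >= min_interior) {
    idx <- seq.int(modwt_filter_width(scale), d$n)
    convention <- "interior"
  } else {
    idx <- seq_len(d$n)
    convention <- "reflection"
  }
  df <- max(round(length(idx) / .modwt_redundancy(scale)), 5L)
  list(idx = idx, df = df, convention = convention)
}

#' Wavelet variance at one or more scales
#'
#' The MODWT variance estimate at scale `j` is the mean of squared detail
#' coefficients over the usable set: boundary-free coefficients when at
#' least 8 exist (unbiased estimator), otherwise all coefficients under
#' reflection boundary handling with a `"banded"` flag.
#'
#' @param x numeric vector/matrix or a `modwt_decomp`.
#' @param scales integer vector of scales (default all levels).
#' @param n_levels levels if `x` must be decomposed first.
#' @return matrix scales x series of variances, with attributes
#'   `log_variance` and `df` / `convention` per scale.
#' @export
wavelet_variance <- function(x, scales = NULL, n_levels = 6L) {
  d <- if (inherits(x, "modwt_decomp")) x else modwt(x, n_levels)
  if (is.null(scales)) scales <- seq_len(d$n_levels)
  out <- matrix(NA_real_, length(scales), ncol(d$V))
  dfs <- integer(length(scales)); conv <- character(length(scales))
  for (i in seq_along(scales)) {
    s <- scales[i]
    sup <- .scale_support(d, s)
    if (length(sup$idx) < 2L) stop("fewer than 2 usable coefficients at scale ", s)
    Wj <- d$W[[s]][sup$idx, , drop = FALSE]
    out[i, ] <- colMeans(Wj^2)
    dfs[i] <- sup$df; conv[i] <- sup$convention
  }
  rownames(out) <- paste0("scale", scales)
  structure(out, log_variance = log(out), df = dfs, convention = conv)
}

#' Wavelet correlation between two series at one scale
#'
#' Pearson correlation of the scale-`j` MODWT detail coefficients, with a
#' Fisher z transform `z = atanh(r) * sqrt(df - 3)`.  Because the MODWT is
#' undecimated, `df` is an effective sample size: the usable coefficient
#' count (boundary-free when available, all coefficients under reflection
#' otherwise) divided by the redundancy of the equivalent level-`j`
#' filter, so that `z` is approximately standard normal under
#' independence.  A correlation of exactly +-1 yields an infinite z,
#' returned as `+-Inf` with `capped = TRUE`.
#'
#' @param x,y numeric series of equal length, or `modwt_decomp`s built with
#'   identical settings.
#' @param scale scale index.
#' @return list with `r`, `z`, `df`, `convention`, `capped`.
#' @export
wavelet_correlation <- function(x, y, scale) {
  dx <- if (inherits(x, "modwt_decomp")) x else modwt(x, scale)
  dy <- if (inherits(y, "modwt_decomp")) y else modwt(y, scale)
  stopifnot(dx$n == dy$n, scale <= dx$n_levels)
  sup <- .scale_support(dx, scale)
  wx <- dx$W[[scale]][sup$idx, 1L]
  wy <- dy$W[[scale]][sup$idx, 1L]
  if (stats::sd(wx) == 0 || stats::sd(wy) == 0)
    stop("zero-variance wavelet coefficients at scale ", scale)
  r <- stats::cor(wx, wy)
  capped <- abs(r) >= 1 - 1e-15
  z <- if (capped) sign(r) * Inf else atanh(r) * sqrt(max(sup$df - 3, 1))
  list(r = r, z = z, df = sup$df, convention = sup$convention, capped = capped)
}

#' All-pairs wavelet correlation matrix at one scale
#'
#' @param X time-by-region matrix or `modwt_decomp` of one.
#' @param scale scale index.
#' @param fisher return Fisher z values instead of r.
#' @return region-by-region symmetric matrix (diagonal `NA`), with
#'   attribute `df`.
#' @export
wavelet_cor_matrix <- function(X, scale, fisher = FALSE) {
  d <- if (inherits(X, "modwt_decomp")) X else modwt(X)
  sup <- .scale_support(d, scale)
  W <- d$W[[scale]][sup$idx, , drop = FALSE]
  R <- stats::cor(W)
  diag(R) <- NA_real_
  if (fisher) {
    R <- atanh(pmin(pmax(R, -1 + 1e-15), 1 - 1e-15)) * sqrt(max(sup$df - 3, 1))
  }
  attr(R, "df") <- sup$df
  attr(R, "convention") <- sup$convention
  R
}
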