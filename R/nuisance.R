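#' Zero-phase Butterworth high-pass filter
#'
#' Fourth-order Butterworth high-pass applied forwards and backwards
#' (zero phase).  Used for the 0.001 Hz stopband on motion series and for
#' detrending framewise displacement before spike detection.
#'
#' @param x numeric vector or time-by-series matrix.
#' @param cutoff_hz cutoff frequency (Hz).
#' @param tr_seconds sampling interval (s).
#' @param order filter order (default 4).
#' @return filtered series, same shape as `x`.
#' @export
highpass_butterworth <- function(x, cutoff_hz, tr_seconds, order = 4L) {
  fs <- 1 / tr_seconds
  Wn <- cutoff_hz / (fs / 2)
  stopifnot(Wn > 0, Wn < 1)
  bf <- signal::butter(order, Wn, type = "high")
  apply_fun <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) apply(x, 2L, apply_fun) else apply_fun(x)
}

#' Detrended framewise displacement
#'
#' Removes the slow component of an FWD trace by zero-phase high-pass
#' filtering, leaving high-frequency excursions (the signal used for
#' motion-spike detection at the 1 mm threshold).
#'
#' @param fwd framewise displacement series (mm).
#' @param tr_seconds sampling interval (s).
#' @param cutoff_hz high-pass cutoff (default 0.01 Hz).
#' @return detrended FWD series.
#' @export
detrend_fwd <- function(fwd, tr_seconds, cutoff_hz = 0.01) {
  highpass_butterworth(fwd, cutoff_hz, tr_seconds)
}

#' Select the noise pool: top-SD candidate series
#'
#' Ranks candidate series by standard deviation and keeps the top 2%
#' (at least one), excluding any series carrying an excluded label (the
#' parcel-level analog of removing amygdala/striatum voxels from a
#' white-matter CompCor mask).
#'
#' @param sd_map named numeric vector of per-series standard deviations.
#' @param labels optional character vector (same length) of series labels.
#' @param exclusion_labels labels to exclude from the pool.
#' @param top_fraction fraction retained (default 0.02).
#' @return integer indices into `sd_map` of the selected series.
#' @export
build_noise_pool <- function(sd_map, labels = NULL,
                             exclusion_labels = character(),
                             top_fraction = 0.02) {
  n <- length(sd_map)
  if (n < 50L) stop("need at least 50 candidate series, got ", n)
  keep <- rep(TRUE, n)
  if (!is.null(labels)) keep <- !(labels %in% exclusion_labels)
  if (!any(keep)) stop("all candidate series are excluded")
  k <- max(1L, floor(top_fraction * n))
  cand <- which(keep)
  cand[order(sd_map[cand], decreasing = TRUE)][seq_len(min(k, length(cand)))]
}

# Raw (non-excess) sample kurtosis: Gaussian = 3.
.raw_kurtosis <- function(x) e1071::kurtosis(x, type = 1L) + 3

#' Detect spike regressors from a noise pool and motion trace
#'
#' Stage-1 spike isolation: (1) PCA on the standardized noise pool and
#' retention of the top `n_components` component series; (2) components
#' with raw kurtosis > 4.5 and at least one |z| > 4.5 time point
#' contribute a spike series keeping only their |z| > 3 entries;
#' (3) frames whose detrended FWD exceeds 1 mm contribute unit motion
#' spike regressors; (4) all spike series are jointly PCA-reduced,
#' keeping components with eigenvalue above `1e-8` times the trace.
#'
#' @param noise_series time x series noise-pool matrix.
#' @param fwd framewise displacement (length `nrow(noise_series) - 1` or
#'   equal; a leading zero is padded if one frame short).
#' @param tr_seconds sampling interval (s).
#' @param n_components PCA components screened for spikes (default 30).
#' @param kurtosis_threshold,z_detect,z_keep,fwd_mm thresholds.
#' @return object of class `spike_regressor_set`: list with `spikes`
#'   (time x k matrix, possibly 0 columns), `component_spikes`,
#'   `motion_spike_frames`, `pca_reduced` flag.
#' @export
detect_spike_regressors <- function(noise_series, fwd = NULL,
                                    tr_seconds = 1.5,
                                    n_components = 30L,
                                    kurtosis_threshold = 4.5,
                                    z_detect = 4.5, z_keep = 3,
                                    fwd_mm = 1) {
  X <- as.matrix(noise_series)
  n <- nrow(X)
  sds <- apply(X, 2L, stats::sd)
  Xs <- scale(X[, sds > 0, drop = FALSE])
  k <- min(n_components, ncol(Xs), n - 1L)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  comp <- pc$x[, seq_len(k), drop = FALSE]
  comp_spikes <- list()
  for (j in seq_len(ncol(comp))) {
    z <- as.numeric(scale(comp[, j]))
    if (.raw_kurtosis(comp[, j]) > kurtosis_threshold && any(abs(z) > z_detect)) {
      s <- ifelse(abs(z) > z_keep, comp[, j], 0)
      comp_spikes[[length(comp_spikes) + 1L]] <- s
    }
  }
  motion_frames <- integer(0)
  motion_spikes <- list()
  if (!is.null(fwd)) {
    if (length(fwd) == n - 1L) fwd <- c(0, fwd)
    stopifnot(length(fwd) == n)
    dtf <- detrend_fwd(fwd, tr_seconds)
    motion_frames <- which(dtf > fwd_mm)
    for (fr in motion_frames) {
      s <- numeric(n); s[fr] <- 1
      motion_spikes[[length(motion_spikes) + 1L]] <- s
    }
  }
  all_spikes <- c(comp_spikes, motion_spikes)
  pca_reduced <- FALSE
  if (length(all_spikes) == 0L) {
    spikes <- matrix(numeric(0), n, 0L)
  } else {
    M <- do.call(cbind, all_spikes)
    if (ncol(M) > 1L) {
      pc2 <- stats::prcomp(M, center = TRUE, scale. = FALSE)
      keep <- pc2$sdev^2 > 1e-8 * sum(pc2$sdev^2)
      spikes <- pc2$x[, keep, drop = FALSE]
      pca_reduced <- TRUE
    } else spikes <- M
    colnames(spikes) <- sprintf("spike_%02d", seq_len(ncol(spikes)))
  }
  structure(list(spikes = spikes,
                 component_spikes = comp_spikes,
                 motion_spike_frames = motion_frames,
                 pca_reduced = pca_reduced),
            class = "spike_regressor_set")
}

#' CompCor component regressors
#'
#' Stage-2 CompCor: PCA of the standardized (spike-cleaned) noise pool,
#' keeping the top `n_components` component series, plus first
#' differences of each (zero-padded to preserve length).
#'
#' @param noise_series time x series matrix.
#' @param n_components number of principal components (default 7).
#' @return time x `2 * n_components` matrix (components then derivatives).
#' @export
compcor_components <- function(noise_series, n_components = 7L) {
  X <- as.matrix(noise_series)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("noise pool contains constant series")
  Xs <- scale(X)
  r <- qr(Xs)$rank
  if (r < n_components)
    stop("noise pool rank ", r, " is below the requested ", n_components,
         " components")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  comp <- pc$x[, seq_len(n_components), drop = FALSE]
  deriv <- apply(comp, 2L, function(v) c(0, diff(v)))
  out <- cbind(comp, deriv)
  colnames(out) <- c(sprintf("compcor_%02d", seq_len(n_components)),
                     sprintf("compcor_deriv_%02d", seq_len(n_components)))
  out
}

#' Principal-component motion regressors
#'
#' From the six rigid-body series plus detrended FWD: high-pass filter
#' (0.001 Hz stopband), expand to the basic and square-root-of-absolute
#' series (14), add first and second differences (42), z-score, PCA, and
#' return the top `n_components` scores.
#'
#' @param params time x 6 rigid-body parameter matrix.
#' @param fwd FWD series (length `nrow(params)` or one frame short).
#' @param tr_seconds sampling interval (s).
#' @param n_components retained PCs (default 7).
#' @param stopband_hz high-pass stopband frequency (default 0.001 Hz).
#' @return time x `n_components` matrix of PC score series, with the
#'   42-column intermediate design as attribute `design_width`.
#' @export
motion_regressors <- function(params, fwd, tr_seconds = 1.5,
                              n_components = 7L, stopband_hz = 0.001) {
  params <- as.matrix(params)
  n <- nrow(params)
  if (length(fwd) == n - 1L) fwd <- c(0, fwd)
  stopifnot(length(fwd) == n, ncol(params) == 6L)
  base <- cbind(params, detrend_fwd(fwd, tr_seconds))
  if (all(apply(base, 2L, stats::sd) == 0))
    stop("all motion series are constant")
  filt <- highpass_butterworth(base, stopband_hz, tr_seconds)
  m14 <- cbind(filt, sqrt(abs(filt)))
  d1 <- apply(m14, 2L, function(v) c(0, diff(v)))
  d2 <- apply(d1, 2L, function(v) c(0, diff(v)))
  m42 <- cbind(m14, d1, d2)
  sds <- apply(m42, 2L, stats::sd)
  m42 <- m42[, sds > 0, drop = FALSE]
  Z <- scale(m42)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  out <- pc$x[, seq_len(k), drop = FALSE]
  colnames(out) <- sprintf("motion_pc_%d", seq_len(k))
  attr(out, "design_width") <- ncol(cbind(m14, d1, d2))
  out
}

#' Assemble a nuisance model
#'
#' @param spike_regressors a `spike_regressor_set` (or NULL).
#' @param compcor_regressors matrix from [compcor_components()].
#' @param motion_regressors matrix from [motion_regressors()].
#' @param task_design optional time x k task design matrix, regressed
#'   jointly with the spikes in stage 1.
#' @return object of class `nuisance_model`.
#' @export
nuisance_model <- function(spike_regressors = NULL,
                           compcor_regressors = NULL,
                           motion_regressors = NULL,
                           task_design = NULL) {
  structure(list(spikes = spike_regressors,
                 compcor = compcor_regressors,
                 motion = motion_regressors,
                 task = task_design),
            class = "nuisance_model")
}

# Residualize Y on design X (with intercept), dropping collinear columns.
.residualize <- function(Y, X, warn_tag = "design") {
  if (is.null(X) || ncol(as.matrix(X)) == 0L) return(Y)
  X <- cbind(intercept = 1, as.matrix(X))
  q <- qr(X)
  if (q$rank < ncol(X)) {
    warning("dropping ", ncol(X) - q$rank, " collinear column(s) from the ",
            warn_tag)
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    q <- qr(X)
  }
  Y - X %*% qr.coef(q, Y)
}

#' Regress a nuisance model out of regional data
#'
#' Two-stage regression preserving the pipeline order: spike regressors
#' and the task design are removed first, then the CompCor + derivative
#' and motion PC regressors are removed from the stage-1 residuals.
#' Residuals are orthogonal to every regressor column.
#'
#' @param data time x region matrix.
#' @param model a [nuisance_model()].
#' @return cleaned matrix, same shape, with attribute `stage1` (the
#'   intermediate spike/task-cleaned matrix).
#' @export
regress_nuisance <- function(data, model) {
  Y <- as.matrix(data)
  stopifnot(inherits(model, "nuisance_model"))
  stage1_design <- cbind(
    if (!is.null(model$spikes)) model$spikes$spikes,
    model$task
  )
  if (!is.null(stage1_design) && nrow(stage1_design) != nrow(Y))
    stop("regressor rows do not match data rows")
  Y1 <- .residualize(Y, stage1_design, "stage-1 design")
  stage2_design <- cbind(model$compcor, model$motion)
  if (!is.null(stage2_design) && nrow(as.matrix(stage2_design)) != nrow(Y))
    stop("regressor rows do not match data rows")
  # orthogonalize stage-2 regressors against the stage-1 design so the
  # second regression cannot reintroduce spike/task variance
  if (!is.null(stage2_design) && !is.null(stage1_design))
    stage2_design <- .residualize(stage2_design, stage1_design,
                                  "stage-2 design")
  Y2 <- .residualize(Y1, stage2_design, "stage-2 design")
  dimnames(Y2) <- dimnames(Y)
  attr(Y2, "stage1") <- Y1
  Y2
}

#' Run the full nuisance pipeline on one subject/sequence
#'
#' Convenience wrapper: selects the noise pool from candidate series,
#' detects spikes, derives CompCor and motion regressors, and cleans the
#' regional matrix.
#'
#' @param data time x region matrix.
#' @param noise_candidates time x series candidate noise matrix (with
#'   optional `labels` attribute).
#' @param motion list with `fwd` and `params`.
#' @param tr_seconds sampling interval.
#' @param task_design optional task design matrix.
#' @return list with `cleaned`, `model`, and `pool_idx`.
#' @export
clean_sequence <- function(data, noise_candidates, motion,
                           tr_seconds = 1.5, task_design = NULL) {
  labels <- attr(noise_candidates, "labels", exact = TRUE)
  sds <- apply(noise_candidates, 2L, stats::sd)
  pool_idx <- build_noise_pool(sds, labels,
                               exclusion_labels = "excluded_analog",
                               top_fraction = 0.25)
  pool <- noise_candidates[, pool_idx, drop = FALSE]
  spikes <- detect_spike_regressors(pool, motion$fwd, tr_seconds)
  pool_clean <- .residualize(pool, spikes$spikes, "spike design")
  cc <- compcor_components(pool_clean, min(7L, ncol(pool_clean) - 1L))
  mo <- motion_regressors(motion$params, motion$fwd, tr_seconds)
  model <- nuisance_model(spikes, cc, mo, task_design)
  list(cleaned = regress_nuisance(data, model), model = model,
       pool_idx = pool_idx)
}
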