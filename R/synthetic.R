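#' Specification of a synthetic multi-sequence cohort
#'
#' Defines the statistical structure of a simulated scanning cohort: a
#' binary group, six sequences per subject with the session's time-point
#' counts, a parcellated signal model with a global mode plus local modes
#' mixed with 1/f-shaped temporal sources, framewise-displacement motion
#' traces with a gamma marginal, and a questionnaire battery with a latent
#' factor structure.  All randomness flows from `seed` through a fixed
#' stream-splitting contract: cohort-level structures, then motion, then
#' BOLD, then behavior, are drawn from streams seeded at `seed + 0..3`,
#' with subjects visited in order within each stream.
#'
#' @param n_per_group subjects per group (group 0 and group 1).
#' @param sequence_lengths time points per sequence; the default
#'   `c(330, 330, 240, 240, 504, 180)` gives 1824 per subject.
#' @param tr_seconds sampling interval (s).
#' @param n_regions parcel count (default 278).
#' @param group_lowfreq_scale multiplicative amplitude applied to the
#'   low-frequency (scales 4-6) signal components of group-1 subjects.
#'   The default plants a group difference of roughly d = 0.8 on
#'   low-frequency log-variance summaries.
#' @param order_variance_slope per-position relative drift in regional
#'   variance: sequence at position `p` is scaled by
#'   `sqrt(1 + slope * (p - 1))`.
#' @param order_meancorr_slope per-position drift in global-mode coupling
#'   strength (additive fraction per position).
#' @param hf_motion_ratio_effect group-1 minus group-0 shift of the log
#'   high-frequency/low-frequency FWD variance ratio.
#' @param n_latent_factors behavior factor count.
#' @param behavior_loadings optional 26 x `n_latent_factors` loading
#'   matrix; the default is a deterministic block structure.
#' @param noise_sd idiosyncratic BOLD noise level.
#' @param subject_amp_sd standard deviation of the log-normal
#'   per-subject signal amplitude factor (between-subject amplitude
#'   heterogeneity; at the default 0.28, a group-1 low-frequency scaling
#'   of 1.25 corresponds to a group difference of roughly d = 0.8 on
#'   log-variance summaries).
#' @param mode_amp_sd standard deviation of the log-normal per-subject
#'   amplitudes of the individual local modes (stable within a subject
#'   across sequences; the source of reliable, region-patterned
#'   individual differences in connectivity).
#' @param subject_motion_sd standard deviation of the log-normal
#'   per-subject motion amplitude and high-frequency-share factors.
#' @param behavior_noise_sd idiosyncratic questionnaire noise level.
#' @param gs_strength amplitude of the global mode.
#' @param n_local_modes number of local spatial modes.
#' @param artifact_strength amplitude of a planted broadband artifact that
#'   dominates the noise pool and leaks into regional data (the target of
#'   CompCor-style cleaning).
#' @param spike_rate per-frame probability of a motion spike (> 1 mm).
#' @param n_noise_pool size of the white-matter-analog noise pool.
#' @param fwd_gamma_shape,fwd_gamma_scale gamma marginal of FWD (mm).
#' @param seed integer RNG seed (< 2^31 - 10).
#' @param structure_seed seed of the cohort-level spatial structures
#'   (global-mode region weights, local-mode mixing, artifact
#'   topography).  Held fixed by default so independently seeded
#'   cohorts share the same "anatomy", the way two samples scanned with
#'   the same parcellation do; vary it to resample the spatial
#'   organization itself.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 30L,
                        sequence_lengths = c(330L, 330L, 240L, 240L, 504L, 180L),
                        tr_seconds = 1.5,
                        n_regions = 278L,
                        group_lowfreq_scale = 1.25,
                        order_variance_slope = 0.05,
                        order_meancorr_slope = -0.03,
                        hf_motion_ratio_effect = 0,
                        n_latent_factors = 4L,
                        behavior_loadings = NULL,
                        noise_sd = 1,
                        subject_amp_sd = 0.28,
                        mode_amp_sd = 0.4,
                        subject_motion_sd = 0.3,
                        behavior_noise_sd = 0.5,
                        gs_strength = 1,
                        n_local_modes = 8L,
                        artifact_strength = 1,
                        spike_rate = 0.002,
                        n_noise_pool = 60L,
                        fwd_gamma_shape = 2,
                        fwd_gamma_scale = 0.1,
                        seed = 1L,
                        structure_seed = 360L) {
  if (any(sequence_lengths < 64L)) stop("all sequence lengths must be >= 64")
  if (n_regions < 4L) stop("n_regions must be >= 4")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (group_lowfreq_scale <= 0) stop("group_lowfreq_scale must be positive")
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (seed >= 2^31 - 10) stop("seed must be below 2^31 - 10")
  if (!is.null(behavior_loadings)) {
    behavior_loadings <- as.matrix(behavior_loadings)
    if (nrow(behavior_loadings) != 26L)
      stop("behavior_loadings must have 26 rows (questionnaire scales)")
    if (qr(behavior_loadings)$rank < ncol(behavior_loadings))
      warning("behavior_loadings is rank deficient")
    n_latent_factors <- ncol(behavior_loadings)
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    sequence_lengths = as.integer(sequence_lengths),
    tr_seconds = tr_seconds,
    n_regions = as.integer(n_regions),
    group_lowfreq_scale = group_lowfreq_scale,
    order_variance_slope = order_variance_slope,
    order_meancorr_slope = order_meancorr_slope,
    hf_motion_ratio_effect = hf_motion_ratio_effect,
    n_latent_factors = as.integer(n_latent_factors),
    behavior_loadings = behavior_loadings,
    noise_sd = noise_sd,
    subject_amp_sd = subject_amp_sd,
    mode_amp_sd = mode_amp_sd,
    subject_motion_sd = subject_motion_sd,
    behavior_noise_sd = behavior_noise_sd,
    gs_strength = gs_strength,
    n_local_modes = as.integer(n_local_modes),
    artifact_strength = artifact_strength,
    spike_rate = spike_rate,
    n_noise_pool = as.integer(n_noise_pool),
    fwd_gamma_shape = fwd_gamma_shape,
    fwd_gamma_scale = fwd_gamma_scale,
    seed = as.integer(seed),
    structure_seed = as.integer(structure_seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec: ", 2L * x$n_per_group, " subjects (",
      x$n_per_group, "/group), ", length(x$sequence_lengths),
      " sequences, ", x$n_regions, " regions, TR = ", x$tr_seconds,
      " s, seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Default deterministic questionnaire loading structure: each factor loads
# 0.8 on its own block of scales and 0.1 elsewhere.
.default_behavior_loadings <- function(k) {
  L <- matrix(0.1, 26L, k)
  if (k == 1L) { L[] <- 0.8; return(L) }
  blocks <- split(seq_len(26L), cut(seq_len(26L), k, labels = FALSE))
  for (f in seq_len(k)) L[blocks[[f]], f] <- 0.8
  L
}

# Scale the low-frequency band (wavelet scales 4-6, f in (2^-7, 2^-4]
# cycles per sample) of every column by `gain`, leaving the rest of the
# spectrum untouched.  Applied to group-1 noise so the planted group
# effect is a uniform amplitude scaling of all low-frequency content --
# a scaling that per-region z-transformation removes.
.scale_lowfreq_band <- function(E, gain) {
  if (gain == 1) return(E)
  n <- nrow(E)
  F <- stats::mvfft(E)
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  keep <- f > 2^-7 & f <= 2^-4
  band <- Re(stats::mvfft(F * keep, inverse = TRUE)) / n
  E + (gain - 1) * band
}

# Cohort-level spatial structures, drawn from the structure seed (shared
# across cohorts by default: the synthetic "anatomy").
.cohort_structures <- function(spec) {
  set.seed(spec$structure_seed)
  P <- spec$n_regions
  k <- spec$n_local_modes
  list(
    gs_weights = stats::runif(P, 0.5, 1.5),
    local_mix = matrix(stats::rnorm(P * k, sd = 0.6), P, k),
    artifact_weights = stats::runif(P, 0.1, 0.4),
    pool_artifact_weights = stats::runif(spec$n_noise_pool, 0.8, 1.2),
    pool_labels = c(rep("excluded_analog", 4L),
                    rep("wm_analog", spec$n_noise_pool - 4L))
  )
}

# 1/f-shaped temporal source: white noise split into the six dyadic
# octave bands (brickwall FFT filters), reweighted so each band carries
# the same variance.  Returns the low-frequency (bands 4-6) part
# separately so group scaling of that component is exact and
# recoverable.
.make_sources <- function(n, n_series, lowfreq_gain) {
  noise <- matrix(stats::rnorm(n * n_series), n, n_series)
  F <- stats::mvfft(noise)
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  w <- 2^((1:6) / 2)
  w <- w / sqrt(sum(w^2) / 6)
  src <- matrix(0, n, n_series)
  low <- matrix(0, n, n_series)
  for (j in 1:6) {
    lo <- 2^-(j + 1); hi <- 2^-j
    keep <- if (j < 6L) (f > lo & f <= hi) else (f <= hi & f > 0)
    Fb <- F * keep
    band <- w[j] * Re(stats::mvfft(Fb, inverse = TRUE)) / n
    if (j >= 4) {
      band <- band * lowfreq_gain
      low <- low + band
    }
    src <- src + band
  }
  list(sources = src, lowfreq_part = low)
}

#' Generate a full synthetic cohort
#'
#' Draws motion traces, regional BOLD matrices, a noise pool, and a
#' behavior table for `2 * n_per_group` subjects under the structure
#' encoded in `spec`.  Latent components (global and local sources, the
#' planted artifact, mixing weights) are stored so downstream estimators
#' can be checked against ground truth.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `gs_cohort`: list with `bold` (subject ->
#'   sequence -> time x region matrix), `noise_pool`, `motion` (subject ->
#'   sequence -> list(fwd, params)), `behavior` (data frame), `group`,
#'   `latents`, `structures`, and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  st <- .cohort_structures(spec)
  motion <- generate_fwd_series(spec)
  bold <- .generate_bold_internal(spec, st, motion)
  behavior <- generate_behavior(spec)
  structure(list(
    bold = bold$bold,
    noise_pool = bold$noise_pool,
    latents = bold$latents,
    motion = motion,
    behavior = behavior,
    group = rep(c(0L, 1L), each = spec$n_per_group),
    structures = st,
    spec = spec
  ), class = "gs_cohort")
}

#' @export
print.gs_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", length(x$bold), " subjects x ",
      length(x$spec$sequence_lengths), " sequences x ",
      x$spec$n_regions, " regions\n", sep = "")
  invisible(x)
}

#' Generate regional BOLD time series for a cohort
#'
#' Convenience wrapper returning only the BOLD portion of
#' [generate_cohort()]; group-1 subjects' low-frequency (scales 4-6)
#' signal components are scaled by `group_lowfreq_scale`, regional
#' variance drifts across sequence position by `order_variance_slope`,
#' and global-mode coupling drifts by `order_meancorr_slope`.
#'
#' @param spec a [cohort_spec()].
#' @return list per subject of lists per sequence of time x region
#'   matrices, with `group` attribute.
#' @export
generate_regional_bold <- function(spec) {
  st <- .cohort_structures(spec)
  motion <- generate_fwd_series(spec)
  b <- .generate_bold_internal(spec, st, motion)
  structure(b$bold, group = rep(c(0L, 1L), each = spec$n_per_group),
            latents = b$latents)
}

.generate_bold_internal <- function(spec, st, motion) {
  set.seed(spec$seed + 2L)
  n_subj <- 2L * spec$n_per_group
  group <- rep(c(0L, 1L), each = spec$n_per_group)
  P <- spec$n_regions
  bold <- vector("list", n_subj)
  pool <- vector("list", n_subj)
  latents <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    gain <- if (group[s] == 1L) spec$group_lowfreq_scale else 1
    amp <- exp(stats::rnorm(1L, 0, spec$subject_amp_sd))
    mode_amp <- exp(stats::rnorm(spec$n_local_modes, 0, spec$mode_amp_sd))
    seqs <- vector("list", length(spec$sequence_lengths))
    pools <- vector("list", length(spec$sequence_lengths))
    lat <- vector("list", length(spec$sequence_lengths))
    for (q in seq_along(spec$sequence_lengths)) {
      n <- spec$sequence_lengths[q]
      src <- .make_sources(n, 1L + spec$n_local_modes, gain)
      g_t <- src$sources[, 1L]
      locals <- src$sources[, -1L, drop = FALSE] %*% diag(mode_amp)
      gs_gain <- spec$gs_strength * (1 + spec$order_meancorr_slope * (q - 1))
      art <- .make_sources(n, 1L, 1)$sources[, 1L]
      signal <- amp * (outer(g_t, st$gs_weights * gs_gain) +
        locals %*% t(st$local_mix))
      eps <- .scale_lowfreq_band(matrix(stats::rnorm(n * P), n, P), gain)
      X <- signal +
        spec$artifact_strength * outer(art, st$artifact_weights) +
        spec$noise_sd * eps
      # order-position variance drift
      mult <- sqrt(1 + spec$order_variance_slope * (q - 1))
      X <- X * mult
      colnames(X) <- sprintf("region_%03d", seq_len(P))
      # noise pool: dominated by the artifact, plus spikes at high-motion
      # frames in a subset of series
      np <- spec$artifact_strength * outer(art, st$pool_artifact_weights) +
        0.5 * matrix(stats::rnorm(n * spec$n_noise_pool), n, spec$n_noise_pool)
      fwd_full <- c(0, motion[[s]][[q]]$fwd)
      spike_frames <- which(fwd_full > 1)
      if (length(spike_frames) > 0) {
        hit <- seq_len(min(6L, spec$n_noise_pool))
        spike_amp <- 6 + stats::rexp(length(spike_frames) * length(hit), 1)
        np[spike_frames, hit] <- np[spike_frames, hit] +
          matrix(spike_amp, length(spike_frames), length(hit)) *
            sample(c(-1, 1), length(spike_frames) * length(hit), replace = TRUE)
      }
      colnames(np) <- sprintf("pool_%03d", seq_len(spec$n_noise_pool))
      seqs[[q]] <- X
      pools[[q]] <- structure(np, labels = st$pool_labels)
      lf <- src$lowfreq_part
      lf[, -1L] <- lf[, -1L, drop = FALSE] %*% diag(mode_amp)
      lat[[q]] <- list(global = g_t * gs_gain * mult * amp,
                       locals = locals * mult * amp,
                       lowfreq_sources = lf * mult * amp,
                       artifact = art * mult * spec$artifact_strength,
                       order_multiplier = mult,
                       subject_amp = amp)
    }
    bold[[s]] <- seqs
    pool[[s]] <- pools
    latents[[s]] <- lat
  }
  list(bold = bold, noise_pool = pool, latents = latents)
}

#' Reconstruct the latent regional signal component
#'
#' Rebuilds, from stored latent sources and cohort mixing structures, the
#' noise-free signal part (global + local modes, after group and order
#' scaling) of one subject/sequence matrix.  Used as an oracle in tests.
#'
#' @param cohort a `gs_cohort`.
#' @param subject,sequence indices.
#' @param component `"signal"`, `"lowfreq"` (scales 4-6 part only),
#'   `"global"`, or `"artifact"`.
#' @return time x region matrix (or vector for `"global"`/`"artifact"`).
#' @export
latent_component <- function(cohort, subject, sequence,
                             component = c("signal", "lowfreq", "global",
                                           "artifact")) {
  component <- match.arg(component)
  lat <- cohort$latents[[subject]][[sequence]]
  st <- cohort$structures
  spec <- cohort$spec
  gs_gain <- spec$gs_strength *
    (1 + spec$order_meancorr_slope * (sequence - 1))
  switch(component,
    global = lat$global,
    artifact = outer(lat$artifact, st$artifact_weights),
    signal = outer(lat$global, st$gs_weights) +
      lat$locals %*% t(st$local_mix),
    lowfreq = outer(lat$lowfreq_sources[, 1L] * gs_gain, st$gs_weights) +
      lat$lowfreq_sources[, -1L, drop = FALSE] %*% t(st$local_mix)
  )
}

#' Generate framewise-displacement motion traces
#'
#' FWD has a gamma marginal (copula-transformed from a Gaussian base that
#' mixes a high-frequency and an AR(1) low-frequency component) with an
#' optional Bernoulli spike process adding excursions above 1 mm.  Group 1
#' receives a shift of `hf_motion_ratio_effect` on the log high/low
#' frequency variance ratio of the Gaussian base.  Six rigid-body
#' parameter series (3 translations in mm, 3 rotations in rad) are slow
#' AR(1) drifts plus high-frequency noise.  FWD has length `n - 1`
#' (displacement between consecutive frames); helpers pad a leading zero
#' when frame alignment is required.
#'
#' @param spec a [cohort_spec()].
#' @return list per subject of lists per sequence of
#'   `list(fwd, params)`, with `group` attribute.
#' @export
generate_fwd_series <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 1L)
  n_subj <- 2L * spec$n_per_group
  group <- rep(c(0L, 1L), each = spec$n_per_group)
  out <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    hf_mult <- exp(stats::rnorm(1L, 0, spec$subject_motion_sd))
    amp_mult <- exp(stats::rnorm(1L, 0, spec$subject_motion_sd))
    w_hf <- hf_mult *
      (if (group[s] == 1L) exp(spec$hf_motion_ratio_effect / 2) else 1)
    seqs <- vector("list", length(spec$sequence_lengths))
    for (q in seq_along(spec$sequence_lengths)) {
      n <- spec$sequence_lengths[q]
      m <- n - 1L
      hf <- stats::rnorm(m)
      lf <- as.numeric(stats::arima.sim(list(ar = 0.95), m,
                                        sd = sqrt(1 - 0.95^2)))
      z <- (w_hf * hf + lf) / sqrt(w_hf^2 + 1)
      fwd <- stats::qgamma(stats::pnorm(z), shape = spec$fwd_gamma_shape,
                           scale = spec$fwd_gamma_scale * amp_mult)
      spikes <- which(stats::rbinom(m, 1L, spec$spike_rate) == 1L)
      if (length(spikes) > 0)
        fwd[spikes] <- fwd[spikes] + 1 + stats::rexp(length(spikes), 2)
      params <- vapply(seq_len(6L), function(p) {
        scale <- if (p <= 3L) 0.08 else 0.0015
        drift <- as.numeric(stats::arima.sim(list(ar = 0.99), n,
                                             sd = sqrt(1 - 0.99^2)))
        scale * (drift + 0.3 * stats::rnorm(n))
      }, numeric(n))
      colnames(params) <- c("trans_x", "trans_y", "trans_z",
                            "rot_x", "rot_y", "rot_z")
      seqs[[q]] <- list(fwd = fwd, params = params)
    }
    out[[s]] <- seqs
  }
  structure(out, group = group)
}

#' Generate a behavior/demographics table
#'
#' 26 questionnaire scale columns are generated as factor loadings times
#' latent factors plus noise, then z-transformed; age, sex (= group) and
#' education complete the 29 analysis columns.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `subject`, `group`, `age`, `sex`,
#'   `education`, and `scale_01` .. `scale_26`.
#' @export
generate_behavior <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 3L)
  n_subj <- 2L * spec$n_per_group
  L <- spec$behavior_loadings
  if (is.null(L)) L <- .default_behavior_loadings(spec$n_latent_factors)
  F <- matrix(stats::rnorm(n_subj * ncol(L)), n_subj, ncol(L))
  scales <- F %*% t(L) +
    spec$behavior_noise_sd * matrix(stats::rnorm(n_subj * 26L), n_subj, 26L)
  if (stats::sd(as.numeric(scales)) > 0) scales <- scale(scales)
  colnames(scales) <- sprintf("scale_%02d", seq_len(26L))
  group <- rep(c(0L, 1L), each = spec$n_per_group)
  data.frame(
    subject = sprintf("sub-%03d", seq_len(n_subj)),
    group = group,
    sex = group,
    age = round(stats::rnorm(n_subj, 21.7, 2), 1),
    education = pmax(1L, round(stats::rnorm(n_subj, 5.5, 1.1))),
    scales,
    check.names = FALSE
  )
}

#' Columns of the behavior table entering multivariate analyses
#'
#' The 26 z-scored questionnaire scales plus age, sex, and education
#' (29 columns).
#'
#' @param behavior data frame from [generate_behavior()].
#' @return numeric matrix with 29 columns.
#' @export
behavior_matrix <- function(behavior) {
  cols <- c(sprintf("scale_%02d", 1:26), "age", "sex", "education")
  as.matrix(behavior[, cols])
}

#' Simulate fractional Brownian motion
#'
#' Exact circulant-embedding (Davies-Harte) simulation of fractional
#' Gaussian noise, cumulated to fractional Brownian motion with Hurst
#' exponent `H`.
#'
#' @param n number of points.
#' @param H Hurst exponent in (0, 1).
#' @return numeric vector of length `n`.
#' @export
simulate_fbm <- function(n, H) {
  stopifnot(H > 0, H < 1, n >= 2)
  m <- n - 1L
  gamma_k <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                                  abs(k - 1)^(2 * H))
  r <- gamma_k(0:m)
  circ <- c(r, rev(r[2:m]))
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0] <- 0
  M <- length(circ)
  z <- stats::rnorm(M) + 1i * stats::rnorm(M)
  w <- stats::fft(sqrt(lambda / (2 * M)) * z)
  fgn <- sqrt(2) * Re(w)[seq_len(m)]
  c(0, cumsum(fgn))
}
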