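# Independent brute-force MODWT oracle: builds the equivalent level-j
# wavelet filter by explicit convolution of upsampled base filters and
# applies it by direct circular convolution to the reflection-extended
# series.  Shares no code with the pyramid implementation beyond the
# filter coefficients themselves.
oracle_modwt <- function(x, n_levels) {
  flt <- la8_filters()
  upsample <- function(f, j) {
    if (j == 1L) return(f)
    out <- numeric((length(f) - 1L) * 2L^(j - 1L) + 1L)
    out[seq(1L, length(out), by = 2L^(j - 1L))] <- f
    out
  }
  conv_full <- function(a, b) {
    n <- length(a) + length(b) - 1L
    out <- numeric(n)
    for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
        out[i:(i + length(b) - 1L)] + a[i] * b
    out
  }
  circ_filter <- function(x, f) {
    N <- length(x)
    out <- numeric(N)
    for (t in seq_len(N)) {
      idx <- ((t - seq_along(f)) %% N) + 1L
      out[t] <- sum(f * x[idx])
    }
    out
  }
  xe <- c(x, rev(x))
  W <- vector("list", n_levels)
  g_casc <- 1
  for (j in seq_len(n_levels)) {
    hj <- conv_full(g_casc, upsample(flt$h, j))
    W[[j]] <- circ_filter(xe, hj)[seq_along(x)]
    g_casc <- conv_full(g_casc, upsample(flt$g, j))
  }
  W
}

# Brickwall FFT band-pass variance: fraction of variance of `x` in the
# frequency band (f_low, f_high], in cycles per sample.
oracle_band_variance <- function(x, f_low, f_high) {
  n <- length(x)
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  sum(sp[f > f_low & f <= f_high]) / n
}

cohens_d <- function(x, g) {
  m <- tapply(x, g, mean); v <- tapply(x, g, var); n <- table(g)
  unname((m[2] - m[1]) / sqrt(((n[1] - 1) * v[1] + (n[2] - 1) * v[2]) /
                                (sum(n) - 2)))
}

# Small cohort spec used across tests (kept tiny for speed).
tiny_spec <- function(seed = 1L, n_per_group = 4L, ...) {
  cohort_spec(n_per_group = n_per_group, n_regions = 12L,
              sequence_lengths = c(128L, 128L, 96L, 96L, 160L, 80L),
              seed = seed, ...)
}
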