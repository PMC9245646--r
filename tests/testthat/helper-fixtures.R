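# shared fixtures, built in code at test time

# a recording whose 22 channels are white noise (fast to build, valid montage)
noise_recording <- function(n_sec = 60, fs = 256, sd = 10, seed = 1) {
  set.seed(seed)
  n <- as.integer(n_sec * fs)
  stages <- rep("N2", max(1, floor(n_sec / 30)))
  recording(matrix(rnorm(22 * n, sd = sd), 22), fs = fs,
            labels = default_channel_labels(), stages = stages)
}

# random stable VAR coefficient array: scale a random draw until the
# companion spectral radius is below the target
random_stable_var <- function(n, p, radius = 0.8, seed = 1) {
  set.seed(seed)
  A <- array(rnorm(n * n * p, sd = 0.3 / p), dim = c(n, n, p))
  rho <- soflow:::var_spectral_radius(A)
  A * (radius / rho)
}

# literal re-implementation of the GPDC definition, evaluated entry by
# entry with explicit loops -- the independent oracle for the vectorised
# pipeline version
gpdc_oracle <- function(A, Sigma, freqs) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1))
  n <- dim(A)[1]; p <- dim(A)[3]
  out <- array(NA_real_, dim = c(n, n, length(freqs)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    Abar <- matrix(0i, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- 0i
      for (k in seq_len(p)) s <- s + A[i, j, k] * exp(-2i * pi * f * k)
      Abar[i, j] <- (if (i == j) 1 else 0) - s
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      # weights are inverse innovation standard deviations squared,
      # i.e. 1 / sigma_kk^2 with sigma_kk = sqrt(Sigma_kk)
      denom <- 0
      for (k in seq_len(n))
        denom <- denom + (1 / Sigma[k, k]) * Mod(Abar[k, j])^2
      out[i, j, fi] <- (1 / sqrt(Sigma[i, i])) * Mod(Abar[i, j]) / sqrt(denom)
    }
  }
  out
}

# embed SO-like waveforms at given trough times into a zero background and
# return the "filtered" detection trace directly (tests construct the band-
# limited trace themselves, as the detector contract allows)
embed_waves <- function(waves, trough_times, n_sec, fs = 256) {
  x <- numeric(as.integer(n_sec * fs))
  for (i in seq_along(waves)) {
    w <- waves[[i]]
    ti <- attr(w, "trough_index")
    i0 <- as.integer(round(trough_times[i] * fs)) + 1L - ti + 1L
    x[seq(i0, i0 + length(w) - 1L)] <- x[seq(i0, i0 + length(w) - 1L)] + w
  }
  x
}
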