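# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: lm() instead of hand-solved normal equations, direct
# monomial-basis least squares instead of the orthogonal recursion, and a
# literal step-by-step transcription of the SNR stopping rule.

# Naive SNR stopping rule: sort, test rank 2 with the bootstrap factor, then
# walk k = 3..N refitting lm(I ~ rank) each step.
oracle_xu <- function(ints, snr_min, rho) {
  I <- sort(ints)
  N <- length(I)
  if (I[2] / ((1 + rho) * I[1]) > snr_min && I[1] > 0) {
    return(list(noise_level = I[1], stop_index = 1L))
  }
  if (I[1] == 0 && I[2] > 0) {  # zero floor: unbounded SNR at rank 2
    return(list(noise_level = I[1], stop_index = 1L))
  }
  if (N >= 3) {
    for (k in 3:N) {
      df <- data.frame(j = seq_len(k - 1), y = I[seq_len(k - 1)])
      fit <- stats::lm(y ~ j, data = df)
      pred <- unname(stats::predict(fit, data.frame(j = k)))
      snr <- if (pred > 0) I[k] / pred else if (I[k] > 0) Inf else 0
      if (snr > snr_min) {
        return(list(noise_level = I[k - 1], stop_index = k - 1L))
      }
    }
  }
  list(noise_level = I[N], stop_index = N)
}

# Direct least squares on the raw monomial basis at the centered design
# points; returns fitted values at the design points.
oracle_ls_fitted <- function(y, degree) {
  x <- seq_along(y) - (length(y) + 1) / 2
  if (degree == 0) return(rep(mean(y), length(y)))
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE))
  unname(stats::fitted(fit))
}

# Evaluate that same monomial-basis fit at arbitrary transformed x.
oracle_ls_predict <- function(y, degree, x_new) {
  x <- seq_along(y) - (length(y) + 1) / 2
  if (degree == 0) return(rep(mean(y), length(x_new)))
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE))
  unname(stats::predict(fit, data.frame(x = x_new)))
}

# Random test spectrum: bounded uniform noise band over a linearly varying
# floor plus a few strong spikes.
random_spectrum <- function(seed, n_noise = 60, n_signal = 6,
                            floor_lo = 10, floor_hi = 100) {
  withr::with_seed(seed, {
    mz <- runif(n_noise + n_signal, 100, 1000)
    floor_at <- floor_lo + (floor_hi - floor_lo) * (mz - 100) / 900
    ints <- floor_at * runif(n_noise + n_signal, 0.4, 1.6)
    sig <- seq_len(n_signal)
    ints[sig] <- floor_at[sig] * 5 * exp(rnorm(n_signal, 0, 0.3))
    spectrum(mz, ints, spectrum_id = sprintf("rand%d", seed))
  })
}

# A peptide drawn from distinct-mass residues (no I, keeps prefix masses
# distinct under rotation).
random_peptide <- function(seed, len = 8) {
  withr::with_seed(seed, {
    pool <- setdiff(names(msnoise::RESIDUE_MASSES), "I")
    peptide(paste(sample(pool, len, replace = TRUE), collapse = ""))
  })
}
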