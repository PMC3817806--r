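# Noise-level estimation by the sorted-intensity SNR stopping rule with
# rank regression (the global method this package's local curve extends).

#' Parameters for the SNR noise estimator
#'
#' @param snr_min dimensionless SNR threshold (> 0). The estimator walks up
#'   the intensity-sorted peaks and stops at the first peak whose observed /
#'   predicted intensity ratio exceeds this. Default 3, the gentle middle of
#'   the 1..11 range usually swept.
#' @param rho dimensionless bootstrap factor (> 0) used to predict the second
#'   smallest intensity before any regression is possible:
#'   `I_hat_2 = (1 + rho) * I_1`. Default 1.
#' @return object of class `XuParams`.
#' @export
xu_params <- function(snr_min = 3, rho = 1) {
  if (!is.numeric(snr_min) || length(snr_min) != 1L || snr_min <= 0) {
    stop("snr_min must be a positive number", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("rho must be a positive number", call. = FALSE)
  }
  structure(list(snr_min = snr_min, rho = rho), class = "XuParams")
}

#' Sort peak intensities ascending, keeping the original-index map
#'
#' @param x a `Spectrum`, a peaks data.frame, or a numeric intensity vector.
#' @return list with `intensity` (ascending, stable for ties) and `index`
#'   (`index[r]` is the original position of the rank-`r` intensity).
#' @export
sort_intensities <- function(x) {
  ints <- peak_intensities(x)
  if (length(ints) < 1) stop("need at least one peak", call. = FALSE)
  ord <- order(ints)  # stable
  list(intensity = ints[ord], index = ord)
}

peak_intensities <- function(x) {
  if (inherits(x, "Spectrum")) x$peaks$intensity
  else if (is.data.frame(x)) x$intensity
  else as.numeric(x)
}

#' Predicted second-rank intensity from the bootstrap factor
#'
#' @param i1 smallest observed intensity (>= 0).
#' @param rho bootstrap factor.
#' @return `(1 + rho) * i1`.
#' @export
predict_k2 <- function(i1, rho) {
  stopifnot(is.numeric(i1), i1 >= 0, is.numeric(rho))
  (1 + rho) * i1
}

#' Least-squares line through intensities indexed by rank
#'
#' Fits `I_j ~ alpha * j + beta` over ranks `j = 1..length(I)` by solving
#' the normal equations with design-matrix rows `(j, 1)`.
#'
#' @param intensities numeric vector of at least 2 rank-ordered intensities.
#' @return named numeric `c(alpha =, beta =)`.
#' @export
fit_rank_regression <- function(intensities) {
  m <- length(intensities)
  if (m < 2) stop("rank regression needs at least 2 points", call. = FALSE)
  A <- cbind(seq_len(m), 1)
  coef <- solve(crossprod(A), crossprod(A, intensities))
  c(alpha = coef[1, 1], beta = coef[2, 1])
}

# SNR of an observed intensity against a predicted one; a non-positive
# prediction under a positive observation counts as unbounded SNR.
snr_ratio <- function(obs, pred) {
  if (pred > 0) obs / pred else if (obs > 0) Inf else 0
}

#' Estimate the noise level of a peak set
#'
#' Intensities are sorted ascending (`I_1 <= ... <= I_N`). The SNR at rank 2
#' is `I_2 / ((1 + rho) I_1)`; if it exceeds `snr_min` the noise level is
#' `I_1`. Otherwise ranks `k = 3..N` are examined in order: a line is fit to
#' `I_1..I_{k-1}` by rank regression, `I_hat_k = alpha k + beta` predicted,
#' and the first `k` with `I_k / I_hat_k > snr_min` stops the scan with the
#' noise level at `I_{k-1}` (the last peak absorbed into the noise). If the
#' rule never fires the whole peak set is noise and the level is `I_N`.
#' Comparisons are strict.
#'
#' @param x a `Spectrum`, peaks data.frame, or numeric intensity vector with
#'   at least 2 peaks.
#' @param params an [xu_params()] object.
#' @return object of class `NoiseEstimate`: list with `noise_level`,
#'   `stop_index` (rank in ascending order at which the level sits),
#'   `alpha`, `beta` (last regression used, `NA` if none), `used_regression`,
#'   `n`, `snr_min`, `rho`.
#' @examples
#' estimate_noise(c(1, 1.5, 2, 100), xu_params(snr_min = 3))
#' @export
estimate_noise <- function(x, params = xu_params()) {
  stopifnot(inherits(params, "XuParams"))
  ints <- peak_intensities(x)
  if (length(ints) < 2) {
    stop("noise estimation needs at least 2 peaks; treat smaller bins as empty",
         call. = FALSE)
  }
  s <- sort_intensities(ints)
  I <- s$intensity
  N <- length(I)

  mk <- function(level, stop_index, alpha, beta, used) {
    structure(list(noise_level = level, stop_index = stop_index,
                   alpha = alpha, beta = beta, used_regression = used,
                   n = N, snr_min = params$snr_min, rho = params$rho),
              class = "NoiseEstimate")
  }

  if (snr_ratio(I[2], predict_k2(I[1], params$rho)) > params$snr_min) {
    return(mk(I[1], 1L, NA_real_, NA_real_, FALSE))
  }
  alpha <- NA_real_
  beta <- NA_real_
  if (N >= 3) {
    # the normal equations of fit_rank_regression, with the rank sums
    # updated incrementally so the scan over k is linear in N
    Sy <- I[1] + I[2]
    Sjy <- I[1] + 2 * I[2]
    for (k in 3:N) {
      m <- k - 1
      Sj <- m * (m + 1) / 2
      Sjj <- m * (m + 1) * (2 * m + 1) / 6
      denom <- m * Sjj - Sj^2
      alpha <- (m * Sjy - Sj * Sy) / denom
      beta <- (Sy * Sjj - Sj * Sjy) / denom
      if (snr_ratio(I[k], alpha * k + beta) > params$snr_min) {
        return(mk(I[k - 1], k - 1L, alpha, beta, TRUE))
      }
      Sy <- Sy + I[k]
      Sjy <- Sjy + k * I[k]
    }
  }
  # rule never fired: the entire peak set is noise
  mk(I[N], N, alpha, beta, N >= 3)
}

#' @export
print.NoiseEstimate <- function(x, ...) {
  cat(sprintf(
    "NoiseEstimate: level %.6g at rank %d of %d (snr_min %.3g, rho %.3g)%s\n",
    x$noise_level, x$stop_index, x$n, x$snr_min, x$rho,
    if (x$used_regression) sprintf("; line %.4g*k + %.4g", x$alpha, x$beta)
    else ""))
  invisible(x)
}
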