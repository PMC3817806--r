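# Smooth noise curve across the spectrum: equal-width m/z bins, per-bin
# noise levels, then least squares on the Gram-Chebyshev orthogonal
# polynomials for equally spaced points, evaluated at every peak's m/z.

#' Partition a spectrum into equally spaced m/z bins
#'
#' Bins span `[min m/z, max m/z]` with equal widths; bins are half-open on
#' the right except the last, which is closed, so every peak lands in
#' exactly one bin.
#'
#' @param spectrum a non-empty `Spectrum`.
#' @param n_bins integer number of bins, >= 2.
#' @return object of class `BinSpec`: list with `n_bins`, `mz_lo`, `mz_hi`,
#'   `edges` (length `n_bins + 1`), `centers`, `width`, and `bin` (bin index
#'   of each peak, in peak order).
#' @export
make_bins <- function(spectrum, n_bins) {
  assert_spectrum(spectrum, 1L, "binning")
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2 ||
      n_bins != round(n_bins)) {
    stop("n_bins must be an integer >= 2", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  mz <- spectrum$peaks$mz
  lo <- min(mz)
  hi <- max(mz)
  if (hi <= lo) {
    stop("binning needs peaks at more than one m/z value", call. = FALSE)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  width <- (hi - lo) / n_bins
  idx <- findInterval(mz, edges, rightmost.closed = TRUE)
  structure(
    list(n_bins = n_bins, mz_lo = lo, mz_hi = hi, edges = edges,
         centers = edges[-1L] - width / 2, width = width, bin = idx),
    class = "BinSpec"
  )
}

#' Per-bin noise levels
#'
#' Runs [estimate_noise()] inside each bin. Bins holding fewer than 2 peaks
#' cannot support the estimator; their level is imputed as the mean of the
#' nearest estimable bins on each side (one side at the extremes).
#'
#' @param spectrum the binned `Spectrum`.
#' @param bins a `BinSpec` from [make_bins()].
#' @param params an [xu_params()] object.
#' @return numeric vector of length `n_bins` with attribute `imputed`
#'   (logical vector marking bins whose level was imputed). All-`NA` when no
#'   bin holds 2 peaks (callers fall back to a global estimate).
#' @export
per_bin_noise <- function(spectrum, bins, params = xu_params()) {
  stopifnot(inherits(bins, "BinSpec"))
  ints <- spectrum$peaks$intensity
  y <- rep(NA_real_, bins$n_bins)
  for (i in seq_len(bins$n_bins)) {
    in_bin <- ints[bins$bin == i]
    if (length(in_bin) >= 2) {
      y[i] <- estimate_noise(in_bin, params)$noise_level
    }
  }
  imputed <- is.na(y)
  if (any(imputed) && !all(imputed)) {
    known <- which(!imputed)
    for (i in which(imputed)) {
      left <- known[known < i]
      right <- known[known > i]
      nb <- c(if (length(left)) y[max(left)], if (length(right)) y[min(right)])
      y[i] <- mean(nb)
    }
  }
  attr(y, "imputed") <- imputed
  y
}

#' Centered design points for n equally spaced observations
#'
#' @param n number of design points, >= 2.
#' @return `x_i = i - (n + 1)/2` for `i = 1..n`: unit spacing, symmetric
#'   about 0; integers for odd `n`, half-integers for even `n`.
#' @export
transform_design <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2, n == round(n))
  seq_len(n) - (n + 1) / 2
}

# Pearson-Hartley integer-scaling constants lambda_j (j = 1..5) for the
# tabulated odd design sizes; lambda = 1 elsewhere (it cancels in the fit).
gram_lambda_table <- list(
  `3`  = c(1, 3),
  `5`  = c(1, 1, 5 / 6, 35 / 12),
  `7`  = c(1, 1, 1 / 6, 7 / 12, 7 / 20),
  `9`  = c(1, 3, 5 / 6, 7 / 12, 3 / 20),
  `11` = c(1, 1, 5 / 6, 1 / 12, 1 / 40)
)

#' Integer-scaling constant for a Gram polynomial
#'
#' @param j polynomial degree (0..5).
#' @param n number of equally spaced design points.
#' @return the tabulated Pearson-Hartley constant for odd `n` in 3..11 and
#'   `1 <= j <= min(5, n - 1)`; 1 otherwise (scaling does not affect the
#'   least-squares fit).
#' @export
gram_lambda <- function(j, n) {
  if (j == 0) return(1)
  tab <- gram_lambda_table[[as.character(n)]]
  if (!is.null(tab) && j <= length(tab)) tab[j] else 1
}

#' Gram-Chebyshev orthogonal polynomial for equally spaced points
#'
#' Evaluates the degree-`j` member of the polynomial system orthogonal under
#' summation over `n` equally spaced points (in the centered unit-spacing
#' coordinate of [transform_design()]), scaled by [gram_lambda()] so that
#' values at the design points of the classical tables are integers.
#'
#' @param j degree, 0..5 (the curve-fitting grid tops out at degree 5).
#' @param x numeric vector of (transformed) abscissae.
#' @param n number of design points; must satisfy `n >= j + 1`.
#' @return numeric vector of polynomial values.
#' @examples
#' gram_poly(2, transform_design(3), 3)   # 1 -2 1
#' @export
gram_poly <- function(j, x, n) {
  if (!is.numeric(j) || length(j) != 1L || j != round(j) || j < 0) {
    stop("degree j must be a non-negative integer", call. = FALSE)
  }
  if (j > 5) {
    stop("degrees above 5 are not supported (no gain was ever observed there)",
         call. = FALSE)
  }
  if (n < j + 1) {
    stop(sprintf("degree %d needs at least %d design points", j, j + 1),
         call. = FALSE)
  }
  core <- switch(as.character(j),
    `0` = rep(1, length(x)),
    `1` = x,
    `2` = x^2 - (n^2 - 1) / 12,
    `3` = x^3 - (3 * n^2 - 7) / 20 * x,
    `4` = x^4 - (3 * n^2 - 13) / 14 * x^2 +
          3 * (n^2 - 1) * (n^2 - 9) / 560,
    `5` = x^5 - 5 * (n^2 - 7) / 18 * x^3 +
          (15 * n^4 - 230 * n^2 + 407) / 1008 * x
  )
  gram_lambda(j, n) * core
}

#' Fit the smooth noise curve to per-bin noise levels
#'
#' Least squares on the orthogonal basis: each coefficient is the printed
#' ratio of sums `beta_j = sum(Y_i psi_j(x_i)) / sum(psi_j(x_i)^2)`, with no
#' matrix inversion. The fitted curve is `sum_j beta_j psi_j(x)`.
#'
#' @param y per-bin noise levels (length `n`, the number of bins).
#' @param degree polynomial degree `k`, `0 <= k <= min(5, n - 1)` (with 3
#'   bins one can have at most a degree-2 polynomial).
#' @param bins optional `BinSpec`; when supplied the curve is anchored in
#'   m/z (design points at bin centers), otherwise it lives on the abstract
#'   coordinate `1..n`.
#' @return object of class `OrthoPolyFit`: list with `n`, `degree`, `y`,
#'   `x_design`, `beta_hat`, `lambda`, `fitted`, `half_range_center`,
#'   `spacing`, `mz_lo`, `mz_hi`.
#' @export
fit_noise_curve <- function(y, degree, bins = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2) stop("need at least 2 bin levels", call. = FALSE)
  if (anyNA(y)) stop("bin levels contain NA; impute before fitting", call. = FALSE)
  if (!is.numeric(degree) || length(degree) != 1L || degree != round(degree) ||
      degree < 0) {
    stop("degree must be a non-negative integer", call. = FALSE)
  }
  if (degree > n - 1) {
    stop(sprintf("degree must be at most n_bins - 1 (= %d)", n - 1),
         call. = FALSE)
  }
  if (degree > 5) stop("degrees above 5 are not supported", call. = FALSE)
  x <- transform_design(n)
  B <- vapply(0:degree, function(j) gram_poly(j, x, n), numeric(n))
  B <- matrix(B, nrow = n)
  beta_hat <- colSums(y * B) / colSums(B^2)
  if (!is.null(bins)) {
    stopifnot(inherits(bins, "BinSpec"), bins$n_bins == n)
    center <- mean(bins$centers)
    spacing <- bins$width
    mz_lo <- bins$mz_lo
    mz_hi <- bins$mz_hi
  } else {
    center <- (n + 1) / 2
    spacing <- 1
    mz_lo <- 1
    mz_hi <- n
  }
  structure(
    list(n = n, degree = as.integer(degree), y = y, x_design = x,
         beta_hat = beta_hat,
         lambda = vapply(0:degree, gram_lambda, numeric(1), n = n),
         fitted = as.vector(B %*% beta_hat),
         half_range_center = center, spacing = spacing,
         mz_lo = mz_lo, mz_hi = mz_hi),
    class = "OrthoPolyFit"
  )
}

#' Evaluate the fitted noise curve at given m/z values
#'
#' The m/z is clamped to the fitted range, transformed to the centered
#' design coordinate, and pushed through the orthogonal polynomial sum;
#' negative curve values are clamped to 0 (a negative noise floor filters
#' nothing).
#'
#' @param fit an `OrthoPolyFit`.
#' @param mz numeric vector of m/z values.
#' @return numeric vector of local noise levels, >= 0.
#' @export
evaluate_noise_curve <- function(fit, mz) {
  stopifnot(inherits(fit, "OrthoPolyFit"))
  mz <- pmin(pmax(as.numeric(mz), fit$mz_lo), fit$mz_hi)
  x <- (mz - fit$half_range_center) / fit$spacing
  val <- numeric(length(x))
  for (j in 0:fit$degree) {
    val <- val + fit$beta_hat[j + 1L] * gram_poly(j, x, fit$n)
  }
  pmax(0, val)
}

#' @export
print.OrthoPolyFit <- function(x, ...) {
  cat(sprintf("OrthoPolyFit: degree %d on %d bins; beta_hat = %s\n",
              x$degree, x$n,
              paste(formatC(x$beta_hat, digits = 5, format = "g"),
                    collapse = ", ")))
  invisible(x)
}
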