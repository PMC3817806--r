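# Filter frontends. Every filter partitions the peak list into retained and
# removed sets; the retention boundary is strictly-greater everywhere (a
# peak exactly at the noise level is itself a noise peak).

new_filter_result <- function(spectrum, keep, method, params,
                              noise_curve = NULL, global_noise_level = NULL) {
  pk <- spectrum$peaks
  pk$peak <- seq_len(nrow(pk))
  structure(
    list(method = method, params = params,
         spectrum_id = spectrum$spectrum_id, n_total = nrow(pk),
         retained = pk[keep, c("peak", "mz", "intensity")],
         removed = pk[!keep, c("peak", "mz", "intensity")],
         noise_curve = noise_curve,
         global_noise_level = global_noise_level),
    class = "FilterResult"
  )
}

#' @export
print.FilterResult <- function(x, ...) {
  cat(sprintf("FilterResult [%s] '%s': %d retained / %d removed of %d\n",
              x$method, x$spectrum_id, nrow(x$retained), nrow(x$removed),
              x$n_total))
  invisible(x)
}

#' Default polynomial degree for a bin count
#'
#' The reference pairing of bins to degree: 3 bins take degree 2, 5 take 4,
#' and 7/9/11 take 5 (beyond degree 5 the curve shape stops changing). Other
#' bin counts take `min(5, n_bins - 1)`.
#'
#' @param n_bins number of bins.
#' @return integer degree.
#' @export
default_degree <- function(n_bins) {
  map <- c(`3` = 2L, `5` = 4L, `7` = 5L, `9` = 5L, `11` = 5L)
  d <- map[as.character(n_bins)]
  if (is.na(d)) d <- as.integer(min(5, n_bins - 1))
  unname(d)
}

#' Filter a spectrum with the local orthogonal-polynomial noise curve
#'
#' Builds equally spaced bins, estimates a noise level in each with the SNR
#' stopping rule, fits the Gram-polynomial noise curve through the per-bin
#' levels, and retains exactly the peaks whose intensity is strictly above
#' the curve at their own m/z.
#'
#' `n_bins = 1` is accepted as the degenerate configuration: a constant
#' curve at the global noise level (degree must be 0), which reproduces
#' [filter_xu_global()].
#'
#' @param spectrum a non-empty `Spectrum`.
#' @param n_bins number of bins (reference grid 3, 5, 7, 9, 11; default 5).
#' @param degree polynomial degree, at most `n_bins - 1`; `NULL` picks
#'   [default_degree()].
#' @param xu an [xu_params()] object for the per-bin estimator.
#' @return a `FilterResult` whose `noise_curve` holds the `OrthoPolyFit`.
#' @examples
#' sim <- simulate_spectrum(simulation_config("SAMPLERK", seed = 7))
#' filter_orthopoly(sim$spectrum, n_bins = 5)
#' @export
filter_orthopoly <- function(spectrum, n_bins = 5, degree = NULL,
                             xu = xu_params()) {
  assert_spectrum(spectrum, 2L, "orthogonal-polynomial filtering")
  if (is.null(degree)) degree <- default_degree(n_bins)
  params <- list(n_bins = n_bins, degree = degree, xu = xu)

  if (n_bins == 1) {
    if (degree != 0) stop("a single bin supports only degree 0", call. = FALSE)
    level <- estimate_noise(spectrum, xu)$noise_level
    keep <- spectrum$peaks$intensity > level
    return(new_filter_result(spectrum, keep, "orthopoly", params,
                             global_noise_level = level))
  }
  if (degree > n_bins - 1) {
    stop(sprintf("degree (%d) must be at most n_bins - 1 (%d)",
                 degree, n_bins - 1), call. = FALSE)
  }
  bins <- make_bins(spectrum, n_bins)
  y <- per_bin_noise(spectrum, bins, xu)
  if (all(is.na(y))) {
    # no bin holds 2 peaks: fall back to a constant curve at the global level
    level <- estimate_noise(spectrum, xu)$noise_level
    keep <- spectrum$peaks$intensity > level
    return(new_filter_result(spectrum, keep, "orthopoly", params,
                             global_noise_level = level))
  }
  fit <- fit_noise_curve(as.numeric(y), degree, bins)
  local_level <- evaluate_noise_curve(fit, spectrum$peaks$mz)
  keep <- spectrum$peaks$intensity > local_level
  new_filter_result(spectrum, keep, "orthopoly", params, noise_curve = fit)
}

#' Filter a spectrum with a single global SNR noise level
#'
#' One [estimate_noise()] over the whole peak list; peaks strictly above the
#' level are retained.
#'
#' @param spectrum a `Spectrum` with at least 2 peaks.
#' @param xu an [xu_params()] object.
#' @return a `FilterResult` with `global_noise_level` set.
#' @export
filter_xu_global <- function(spectrum, xu = xu_params()) {
  assert_spectrum(spectrum, 2L, "global SNR filtering")
  level <- estimate_noise(spectrum, xu)$noise_level
  keep <- spectrum$peaks$intensity > level
  new_filter_result(spectrum, keep, "xu_global", list(xu = xu),
                    global_noise_level = level)
}

#' Filter a spectrum with the lower-half-median baseline
#'
#' The noise level is the median of the lower half (by count) of the
#' intensity values: the `floor(N/2)` smallest intensities, with the median
#' of an even-sized set taken as the mean of its middle pair. Peaks strictly
#' above the level are retained. This baseline has a single fixed
#' parameterization; it supports no SNR adjustment.
#'
#' @param spectrum a `Spectrum` with at least 2 peaks.
#' @return a `FilterResult` with `global_noise_level` set.
#' @export
filter_purvine <- function(spectrum) {
  assert_spectrum(spectrum, 2L, "lower-half-median filtering")
  ints <- sort(spectrum$peaks$intensity)
  lower <- ints[seq_len(floor(length(ints) / 2))]
  level <- stats::median(lower)
  keep <- spectrum$peaks$intensity > level
  new_filter_result(spectrum, keep, "purvine", list(),
                    global_noise_level = level)
}

#' Keep the top percentage of peaks by intensity
#'
#' Retains the `ceiling(percent_kept/100 * N)` highest-intensity peaks
#' (always at least one). Ties at the cut are broken toward higher m/z.
#'
#' @param spectrum a non-empty `Spectrum`.
#' @param percent_kept percentage in `(0, 100]`.
#' @return a `FilterResult`.
#' @export
filter_top_percent <- function(spectrum, percent_kept) {
  assert_spectrum(spectrum, 1L, "top-percent filtering")
  if (!is.numeric(percent_kept) || length(percent_kept) != 1L ||
      percent_kept <= 0 || percent_kept > 100) {
    stop("percent_kept must be in (0, 100]", call. = FALSE)
  }
  n <- n_peaks(spectrum)
  k <- ceiling(percent_kept / 100 * n)
  ord <- order(-spectrum$peaks$intensity, -spectrum$peaks$mz)
  keep <- logical(n)
  keep[ord[seq_len(k)]] <- TRUE
  new_filter_result(spectrum, keep, "top_percent",
                    list(percent_kept = percent_kept))
}
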