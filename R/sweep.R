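# Parameter sweeps over a labeled corpus, in the familiar table layout:
# one row per SNR threshold, one column per method/configuration.

#' Sweep filters over a labeled corpus
#'
#' Runs the lower-half-median baseline, the global SNR filter, and the
#' orthogonal-polynomial filter (one column per bin count) over a corpus at
#' each SNR threshold, and reports the mean retained-signal percentage per
#' cell. Labels come from simulation ground truth when present, otherwise
#' from [classify_peaks()] against a supplied reference peptide.
#'
#' @param corpus a [simulate_corpus()] result, or a list of
#'   `simulate_spectrum()` results, or a list of `Spectrum` objects (then
#'   `pep` is required).
#' @param snr_grid SNR thresholds to sweep; default `c(1, 3, 5, 7, 9, 11)`.
#' @param bins_grid orthogonal-polynomial bin counts; default
#'   `c(3, 5, 7, 9, 11)`.
#' @param degree_map named integer vector mapping bin count to polynomial
#'   degree; default [default_degree()] per bin count.
#' @param rho bootstrap factor for the SNR estimator.
#' @param pep reference peptide for classification when the corpus carries
#'   no ground truth.
#' @param tolerance classification tolerance (amu) when `pep` is used.
#' @return data.frame with column `snr_min` then one column per method
#'   (`purvine`, `xu`, `orthopoly_<bins>`), each cell the mean
#'   `signal_percent` over the corpus.
#' @export
sweep_filters <- function(corpus, snr_grid = c(1, 3, 5, 7, 9, 11),
                          bins_grid = c(3, 5, 7, 9, 11),
                          degree_map = NULL, rho = 1,
                          pep = NULL, tolerance = 0.5) {
  if (is.list(corpus) && !is.null(corpus$spectra)) corpus <- corpus$spectra
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  if (is.null(degree_map)) {
    degree_map <- stats::setNames(vapply(bins_grid, default_degree, integer(1)),
                                  as.character(bins_grid))
  }
  labeled <- lapply(corpus, function(item) {
    if (inherits(item, "Spectrum")) {
      if (is.null(pep)) {
        stop("corpus without ground truth needs a reference peptide",
             call. = FALSE)
      }
      classify_peaks(item, pep, tolerance = tolerance)
    } else if (is.list(item) && inherits(item$spectrum, "Spectrum") &&
               is.data.frame(item$truth)) {
      labels_from_truth(item)
    } else {
      stop("unrecognized corpus element", call. = FALSE)
    }
  })

  cell_mean <- function(filter_fun) {
    vals <- vapply(labeled, function(lb) {
      retention_report(lb, filter_fun(lb$spectrum))$signal_percent
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }

  purvine_val <- cell_mean(filter_purvine)
  out <- data.frame(snr_min = snr_grid)
  out$purvine <- purvine_val  # single fixed parameterization, same all rows
  out$xu <- vapply(snr_grid, function(s) {
    cell_mean(function(sp) filter_xu_global(sp, xu_params(s, rho)))
  }, numeric(1))
  for (b in bins_grid) {
    d <- degree_map[[as.character(b)]]
    out[[sprintf("orthopoly_%d", b)]] <- vapply(snr_grid, function(s) {
      cell_mean(function(sp) {
        filter_orthopoly(sp, n_bins = b, degree = d, xu = xu_params(s, rho))
      })
    }, numeric(1))
  }
  out
}
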