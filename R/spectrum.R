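#' Construct a Spectrum
#'
#' A `Spectrum` is an ordered peak list with optional precursor information.
#' On construction peaks are sorted by m/z (strictly ascending); peaks whose
#' m/z agree to within `1e-6` amu are merged by summing their intensities,
#' so downstream neighborhood logic can assume strict ordering.
#'
#' @param mz numeric vector of mass-to-charge ratios in amu, all > 0.
#' @param intensity numeric vector of non-negative abundances, same length.
#' @param spectrum_id opaque identifier string.
#' @param precursor_mz precursor m/z in amu (> 0), or `NA` if unknown.
#' @param precursor_charge positive integer precursor charge, or `NA`.
#' @param centroided logical; `TRUE` if the peak list has been centroided.
#'
#' @return An object of class `Spectrum`: a list with elements `spectrum_id`,
#'   `peaks` (data.frame with columns `mz`, `intensity`), `precursor_mz`,
#'   `precursor_charge`, `centroided`.
#' @examples
#' s <- spectrum(c(300.1, 100.2, 200.3), c(5, 1, 3))
#' peaks(s)
#' @export
spectrum <- function(mz, intensity, spectrum_id = "spectrum",
                     precursor_mz = NA_real_, precursor_charge = NA_integer_,
                     centroided = TRUE) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) {
    stop("mz and intensity must not contain NA", call. = FALSE)
  }
  if (any(mz <= 0)) stop("all mz values must be > 0", call. = FALSE)
  if (any(intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!is.na(precursor_mz) && precursor_mz <= 0) {
    stop("precursor_mz must be > 0", call. = FALSE)
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  # merge duplicates (<= 1e-6 amu apart) by summing intensity
  if (length(mz) > 1) {
    grp <- cumsum(c(TRUE, diff(mz) > 1e-6))
    if (max(grp) < length(mz)) {
      mz <- as.numeric(tapply(mz, grp, function(x) x[1]))
      intensity <- as.numeric(tapply(intensity, grp, sum))
    }
  }
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      peaks = data.frame(mz = mz, intensity = intensity),
      precursor_mz = as.numeric(precursor_mz),
      precursor_charge = if (is.na(precursor_charge)) NA_integer_
                         else as.integer(precursor_charge),
      centroided = isTRUE(centroided)
    ),
    class = "Spectrum"
  )
}

#' Peak table of a Spectrum
#'
#' @param x a `Spectrum`.
#' @return data.frame with columns `mz` and `intensity`, sorted by m/z.
#' @export
peaks <- function(x) {
  stopifnot(inherits(x, "Spectrum"))
  x$peaks
}

#' Number of peaks in a Spectrum
#'
#' @param x a `Spectrum`.
#' @return integer peak count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "Spectrum"))
  nrow(x$peaks)
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum '%s': %d peaks", x$spectrum_id, n_peaks(x)))
  if (n_peaks(x) > 0) {
    cat(sprintf(", m/z %.4f-%.4f", min(x$peaks$mz), max(x$peaks$mz)))
  }
  if (!is.na(x$precursor_mz)) {
    cat(sprintf("; precursor %.4f", x$precursor_mz))
    if (!is.na(x$precursor_charge)) cat(sprintf(" (%d+)", x$precursor_charge))
  }
  cat(if (x$centroided) "; centroided\n" else "; not centroided\n")
  invisible(x)
}

# internal: insist on a usable, non-empty spectrum
assert_spectrum <- function(x, min_peaks = 1L, what = "this operation") {
  if (!inherits(x, "Spectrum")) {
    stop("expected a Spectrum object", call. = FALSE)
  }
  if (n_peaks(x) < min_peaks) {
    stop(sprintf("%s requires at least %d peak(s); spectrum '%s' has %d",
                 what, min_peaks, x$spectrum_id, n_peaks(x)), call. = FALSE)
  }
  invisible(x)
}
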