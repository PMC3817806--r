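# Readers and writers for the peak-list formats the tool touches:
# MGF (reference), two-column TSV (reference), mzML (optional, via mzR).

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS/END IONS blocks. `PEPMASS` (first token) and `CHARGE`
#' (forms like `2+`, `+2`, `2`) map to the precursor fields; `TITLE` becomes
#' the spectrum id. Peaks are sorted ascending by m/z on ingestion.
#'
#' @param path path to an MGF file.
#' @param centroided logical flag recorded on every spectrum (MGF does not
#'   carry this information).
#' @return list of `Spectrum` objects, one per block (empty list, with a
#'   warning, for an empty file).
#' @export
read_mgf <- function(path, centroided = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning(sprintf("empty MGF file: %s", path))
    return(list())
  }
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop(sprintf("malformed MGF '%s': unbalanced BEGIN IONS/END IONS", path),
         call. = FALSE)
  }
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    body <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    title <- sprintf("index=%d", b)
    pmz <- NA_real_
    pz <- NA_integer_
    mzv <- numeric(0)
    iv <- numeric(0)
    for (ln in body) {
      if (grepl("=", ln, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", ln))
        val <- sub("^[^=]*=", "", ln)
        if (key == "TITLE") title <- val
        if (key == "PEPMASS") {
          pmz <- suppressWarnings(as.numeric(strsplit(trimws(val), "[[:space:]]+")[[1]][1]))
        }
        if (key == "CHARGE") {
          pz <- suppressWarnings(as.integer(gsub("[^0-9]", "", val)))
        }
      } else {
        tok <- strsplit(ln, "[[:space:]]+")[[1]]
        vals <- suppressWarnings(as.numeric(tok[1:2]))
        if (length(tok) < 2 || anyNA(vals)) {
          stop(sprintf("malformed MGF '%s', block %d: bad peak line '%s'",
                       path, b, ln), call. = FALSE)
        }
        mzv <- c(mzv, vals[1])
        iv <- c(iv, vals[2])
      }
    }
    out[[b]] <- spectrum(mzv, iv, spectrum_id = title, precursor_mz = pmz,
                         precursor_charge = pz, centroided = centroided)
  }
  out
}

#' Read a two-column m/z-intensity TSV peak list
#'
#' Tab- or whitespace-separated, two numeric columns, optional header line.
#'
#' @param path path to the file.
#' @param spectrum_id identifier for the resulting spectrum (defaults to the
#'   file name).
#' @param centroided logical centroided flag (default `FALSE`).
#' @return a single `Spectrum`.
#' @export
read_peaklist_tsv <- function(path, spectrum_id = basename(path),
                              centroided = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  start <- 1L
  if (length(lines) >= 1) {
    tok1 <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
    if (anyNA(suppressWarnings(as.numeric(tok1)))) start <- 2L  # header
  }
  mzv <- numeric(0)
  iv <- numeric(0)
  for (i in seq(from = start, length.out = max(0L, length(lines) - start + 1L))) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[1:2]))
    if (length(tok) < 2 || anyNA(vals)) {
      stop(sprintf("parse error in '%s' at line %d: '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    if (vals[2] < 0) {
      stop(sprintf("negative intensity in '%s' at line %d", path, i),
           call. = FALSE)
    }
    mzv <- c(mzv, vals[1])
    iv <- c(iv, vals[2])
  }
  spectrum(mzv, iv, spectrum_id = spectrum_id, centroided = centroided)
}

#' Read spectra from an mzML file
#'
#' Thin wrapper over the mzR parser, exposing mzML behind the same reader
#' interface as [read_mgf()]. MS2 scans only.
#'
#' @param path path to an mzML file.
#' @param centroided default centroided flag where the file does not say.
#' @return list of `Spectrum` objects.
#' @export
read_mzml <- function(path, centroided = TRUE) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the mzR package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  idx <- which(hd$msLevel == 2L)
  lapply(idx, function(i) {
    pk <- mzR::peaks(fh, i)
    cf <- if ("centroided" %in% names(hd) && !is.na(hd$centroided[i])) {
      as.logical(hd$centroided[i])
    } else {
      centroided
    }
    spectrum(pk[, 1], pk[, 2],
             spectrum_id = sprintf("%s scan=%d", basename(path), hd$acquisitionNum[i]),
             precursor_mz = hd$precursorMZ[i],
             precursor_charge = hd$precursorCharge[i],
             centroided = cf)
  })
}

#' Write the retained peaks of a filter result
#'
#' Writes the retained peak set to `path` in MGF or TSV form; TSV output
#' round-trips bit-exactly through [read_peaklist_tsv()]. Removed peaks can
#' optionally be written to a sidecar file in the same format.
#'
#' @param spectrum the original `Spectrum` (source of precursor metadata).
#' @param result a `FilterResult` for that spectrum.
#' @param path output file path.
#' @param format `"tsv"` or `"mgf"`.
#' @param removed_path optional path for the removed peaks.
#' @return `path`, invisibly.
#' @export
write_filtered <- function(spectrum, result, path, format = c("tsv", "mgf"),
                           removed_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(spectrum, "Spectrum"), inherits(result, "FilterResult"))
  if (nrow(result$retained) == 0) {
    warning(sprintf("no peaks retained for spectrum '%s'; writing empty file",
                    spectrum$spectrum_id))
  }
  write_peakset(result$retained, spectrum, path, format)
  if (!is.null(removed_path)) {
    write_peakset(result$removed, spectrum, removed_path, format)
  }
  invisible(path)
}

write_peakset <- function(pk, spectrum, path, format) {
  fmt_num <- function(x) formatC(x, digits = 17, format = "g")
  peak_lines <- paste(fmt_num(pk$mz), fmt_num(pk$intensity), sep = "\t")
  if (format == "tsv") {
    writeLines(peak_lines, path)
  } else {
    hdr <- c("BEGIN IONS", sprintf("TITLE=%s", spectrum$spectrum_id))
    if (!is.na(spectrum$precursor_mz)) {
      hdr <- c(hdr, sprintf("PEPMASS=%s", fmt_num(spectrum$precursor_mz)))
    }
    if (!is.na(spectrum$precursor_charge)) {
      hdr <- c(hdr, sprintf("CHARGE=%d+", spectrum$precursor_charge))
    }
    writeLines(c(hdr, peak_lines, "END IONS"), path)
  }
  invisible(path)
}
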