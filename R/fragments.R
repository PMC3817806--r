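# Theoretical fragment ions for a known peptide and classification of
# observed peaks against them.

#' Theoretical b/y/a fragment ions of a peptide
#'
#' For a peptide of length `L`, generates the `L - 1` b ions (N-terminal
#' residue sums plus a proton), `L - 1` y ions (C-terminal sums plus water
#' plus a proton), and `L - 1` a ions (each b minus CO, 27.99491 amu,
#' nominal 28). With `include_losses`, water (-18.01056) and ammonia
#' (-17.02655) loss variants of the b and y ions are added; `a_ion_losses`
#' extends losses to the a series as well.
#'
#' @param pep a `Peptide` or sequence string, length >= 2.
#' @param charge fragment charge z >= 1 (m/z = (neutral + z protons)/z);
#'   default 1.
#' @param include_losses add water/ammonia loss variants of b and y ions.
#' @param a_ion_losses also add loss variants of a ions.
#' @return data.frame (class `fragment_ions`) with columns `series` ("b",
#'   "y", "a"), `index` (1..L-1), `loss` ("none", "H2O", "NH3"), `charge`,
#'   `mz`, sorted ascending by `mz`.
#' @examples
#' theoretical_ions("GG", include_losses = FALSE)
#' @export
theoretical_ions <- function(pep, charge = 1L, include_losses = TRUE,
                             a_ion_losses = FALSE) {
  pep <- as_peptide(pep)
  r <- residues(pep)
  L <- length(r)
  if (L < 2) stop("fragment generation needs a peptide of length >= 2",
                  call. = FALSE)
  if (!is.numeric(charge) || charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  z <- as.integer(charge)
  masses <- RESIDUE_MASSES[r]
  idx <- seq_len(L - 1)
  b_neutral <- cumsum(masses)[idx]
  y_neutral <- cumsum(rev(masses))[idx] + MASS_CONST[["H2O"]]  # last j residues
  a_neutral <- b_neutral - MASS_CONST[["CO"]]

  ionize <- function(neutral) (neutral + z * MASS_CONST[["proton"]]) / z
  base <- rbind(
    data.frame(series = "b", index = idx, loss = "none", mz = ionize(b_neutral)),
    data.frame(series = "y", index = idx, loss = "none", mz = ionize(y_neutral)),
    data.frame(series = "a", index = idx, loss = "none", mz = ionize(a_neutral))
  )
  out <- base
  if (include_losses) {
    loss_of <- function(df, what) {
      lm <- MASS_CONST[[what]] / z
      transform(df, loss = what, mz = mz - lm)
    }
    with_losses <- base[base$series %in% c("b", "y") |
                          (a_ion_losses & base$series == "a"), ]
    out <- rbind(out, loss_of(with_losses, "H2O"), loss_of(with_losses, "NH3"))
  }
  out$charge <- z
  out <- out[order(out$mz), c("series", "index", "loss", "charge", "mz")]
  rownames(out) <- NULL
  class(out) <- c("fragment_ions", "data.frame")
  out
}

#' Complementary b/y mass sum (annotation sanity identity)
#'
#' `b_i + y_{L-i}` at charge 1 is independent of `i`: it always equals the
#' peptide residue mass + H2O + two protons.
#'
#' @param pep a `Peptide` or sequence string, length >= 2.
#' @param b_index index `i` in `1..L-1`.
#' @return the m/z sum, numeric scalar.
#' @export
complementarity_check <- function(pep, b_index) {
  pep <- as_peptide(pep)
  L <- length(residues(pep))
  if (L < 2) stop("needs a peptide of length >= 2", call. = FALSE)
  if (b_index < 1 || b_index > L - 1) {
    stop(sprintf("b_index must be in 1..%d", L - 1), call. = FALSE)
  }
  ions <- theoretical_ions(pep, include_losses = FALSE)
  b <- ions$mz[ions$series == "b" & ions$index == b_index]
  y <- ions$mz[ions$series == "y" & ions$index == L - b_index]
  b + y
}

# Greedy one-to-one matching of ions to peaks: candidate (peak, ion) pairs
# within tolerance are taken in order of ascending m/z distance, ties broken
# toward higher peak intensity; each ion annotates at most one peak (so one
# fragment cannot inflate the signal count through isotope satellites).
match_ions <- function(pk, ions, tolerance, available) {
  hit <- integer(0)     # peak row
  ion_of <- integer(0)  # ion row
  if (nrow(ions) == 0 || !any(available)) {
    return(data.frame(peak = hit, ion = ion_of))
  }
  cand_peak <- integer(0)
  cand_ion <- integer(0)
  cand_d <- numeric(0)
  av <- which(available)
  for (irow in seq_len(nrow(ions))) {
    d <- abs(pk$mz[av] - ions$mz[irow])
    ok <- which(d <= tolerance)
    cand_peak <- c(cand_peak, av[ok])
    cand_ion <- c(cand_ion, rep(irow, length(ok)))
    cand_d <- c(cand_d, d[ok])
  }
  if (length(cand_peak) == 0) return(data.frame(peak = hit, ion = ion_of))
  ord <- order(cand_d, -pk$intensity[cand_peak])
  peak_used <- logical(nrow(pk))
  ion_used <- logical(nrow(ions))
  for (i in ord) {
    p <- cand_peak[i]
    io <- cand_ion[i]
    if (!peak_used[p] && !ion_used[io]) {
      peak_used[p] <- TRUE
      ion_used[io] <- TRUE
      hit <- c(hit, p)
      ion_of <- c(ion_of, io)
    }
  }
  data.frame(peak = hit, ion = ion_of)
}

#' Classify observed peaks against a known peptide
#'
#' Each peak is matched (greedily, one-to-one, by ascending m/z distance)
#' to the theoretical ions of the peptide within `tolerance`. Peaks matching
#' a plain b or y ion are *primary*; peaks matching an a ion or any
#' water/ammonia loss variant are *secondary* (primary matching takes
#' precedence when a peak lies within tolerance of both). Everything else
#' is *noise*, except that in non-centroided spectra unmatched peaks within
#' `exclusion_window` (default 0.1 amu) of a labeled primary/secondary peak
#' are *excluded* - they are plausibly unresolved satellites of the signal
#' peak and are counted on neither side.
#'
#' @param spectrum a non-empty `Spectrum`.
#' @param pep the reference `Peptide` or sequence string.
#' @param tolerance match tolerance in amu (> 0); default 0.5.
#' @param include_losses generate water/ammonia loss ions (default `TRUE`).
#' @param a_ion_losses also generate losses of a ions (default `FALSE`).
#' @param charge fragment charge (default 1).
#' @param exclusion_window amu window around labeled peaks inside which
#'   unmatched peaks of non-centroided spectra are excluded; default 0.1.
#' @return object of class `LabeledSpectrum`: list with `spectrum`,
#'   `labels` (data.frame: `peak`, `mz`, `intensity`, `label`, `series`,
#'   `index`, `loss`), `peptide`, `tolerance`.
#' @export
classify_peaks <- function(spectrum, pep, tolerance = 0.5,
                           include_losses = TRUE, a_ion_losses = FALSE,
                           charge = 1L, exclusion_window = 0.1) {
  assert_spectrum(spectrum, 1L, "peak classification")
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be > 0", call. = FALSE)
  }
  pep <- as_peptide(pep)
  ions <- theoretical_ions(pep, charge = charge,
                           include_losses = include_losses,
                           a_ion_losses = a_ion_losses)
  primary_ions <- ions[ions$series %in% c("b", "y") & ions$loss == "none", ]
  secondary_ions <- ions[!(ions$series %in% c("b", "y") & ions$loss == "none"), ]

  pk <- spectrum$peaks
  n <- nrow(pk)
  lab <- data.frame(peak = seq_len(n), mz = pk$mz, intensity = pk$intensity,
                    label = rep("noise", n), series = NA_character_,
                    index = NA_integer_, loss = NA_character_)

  avail <- rep(TRUE, n)
  m1 <- match_ions(pk, primary_ions, tolerance, avail)
  if (nrow(m1) > 0) {
    lab$label[m1$peak] <- "primary"
    lab$series[m1$peak] <- primary_ions$series[m1$ion]
    lab$index[m1$peak] <- primary_ions$index[m1$ion]
    lab$loss[m1$peak] <- primary_ions$loss[m1$ion]
    avail[m1$peak] <- FALSE
  }
  m2 <- match_ions(pk, secondary_ions, tolerance, avail)
  if (nrow(m2) > 0) {
    lab$label[m2$peak] <- "secondary"
    lab$series[m2$peak] <- secondary_ions$series[m2$ion]
    lab$index[m2$peak] <- secondary_ions$index[m2$ion]
    lab$loss[m2$peak] <- secondary_ions$loss[m2$ion]
  }

  if (!spectrum$centroided) {
    signal_mz <- lab$mz[lab$label %in% c("primary", "secondary")]
    if (length(signal_mz) > 0) {
      for (i in which(lab$label == "noise")) {
        if (min(abs(signal_mz - lab$mz[i])) <= exclusion_window) {
          lab$label[i] <- "excluded"
        }
      }
    }
  }
  structure(list(spectrum = spectrum, labels = lab, peptide = pep,
                 tolerance = tolerance),
            class = "LabeledSpectrum")
}

#' @export
print.LabeledSpectrum <- function(x, ...) {
  tb <- table(factor(x$labels$label,
                     levels = c("primary", "secondary", "noise", "excluded")))
  cat(sprintf(
    "LabeledSpectrum '%s' vs %s: %d primary, %d secondary, %d noise, %d excluded\n",
    x$spectrum$spectrum_id,
    if (is.null(x$peptide)) "(ground truth)" else unclass(x$peptide),
    tb[["primary"]], tb[["secondary"]], tb[["noise"]], tb[["excluded"]]))
  invisible(x)
}
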