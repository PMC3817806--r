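# Evaluation metrics: signal retention after filtering, and the
# mass-position-aware amino-acid match score for de novo candidates.

#' Signal-retention report for a filtered, labeled spectrum
#'
#' Counts primary/secondary/noise/excluded peaks before and after filtering
#' and reports `signal_percent`, the percentage of retained peaks that are
#' signal: `100 * (primary + secondary) / (primary + secondary + noise)` on
#' the retained set. Excluded peaks (the 0.1 amu satellites of
#' non-centroided data) enter neither numerator nor denominator.
#' `signal_to_noise_percent` reports the alternative normalization
#' `100 * (primary + secondary) / noise`.
#'
#' @param labeled a `LabeledSpectrum` of the unfiltered spectrum.
#' @param result a `FilterResult` computed on the same spectrum.
#' @return object of class `RetentionReport`: list with `before` and
#'   `after` count vectors (`total`, `primary`, `secondary`, `noise`,
#'   `excluded`), `signal_percent`, `signal_to_noise_percent`, and
#'   `primary_loss_percent` (share of pre-filter primary peaks removed).
#' @export
retention_report <- function(labeled, result) {
  stopifnot(inherits(labeled, "LabeledSpectrum"),
            inherits(result, "FilterResult"))
  if (nrow(labeled$labels) != result$n_total ||
      labeled$spectrum$spectrum_id != result$spectrum_id) {
    stop("labels and filter result refer to different spectra", call. = FALSE)
  }
  count <- function(lab) {
    f <- factor(lab, levels = c("primary", "secondary", "noise", "excluded"))
    tb <- table(f)
    c(total = length(lab), primary = unname(tb[["primary"]]),
      secondary = unname(tb[["secondary"]]), noise = unname(tb[["noise"]]),
      excluded = unname(tb[["excluded"]]))
  }
  before <- count(labeled$labels$label)
  post_lab <- labeled$labels$label[result$retained$peak]
  after <- count(post_lab)
  sig <- after[["primary"]] + after[["secondary"]]
  denom <- sig + after[["noise"]]
  structure(
    list(before = before, after = after,
         signal_percent = if (denom > 0) 100 * sig / denom else NA_real_,
         signal_to_noise_percent =
           if (after[["noise"]] > 0) 100 * sig / after[["noise"]] else Inf,
         primary_loss_percent =
           if (before[["primary"]] > 0) {
             100 * (before[["primary"]] - after[["primary"]]) / before[["primary"]]
           } else 0),
    class = "RetentionReport"
  )
}

#' @export
print.RetentionReport <- function(x, ...) {
  cat(sprintf(
    "RetentionReport: %d/%d peaks retained; signal %.2f%% of retained; %.2f%% of primary peaks lost\n",
    x$after[["total"]], x$before[["total"]], x$signal_percent,
    x$primary_loss_percent))
  invisible(x)
}

#' Mass-position-aware amino-acid match score
#'
#' Scores a candidate sequence against a known reference. A candidate
#' residue matches if some reference residue has the same letter *and*
#' occupies the same place in terms of peptide mass: both its start mass
#' (prefix mass before the residue) and end mass (prefix mass after it)
#' agree with the reference residue's within `mass_tolerance`. Each
#' reference residue can be matched at most once. The percentage uses the
#' *reference* length as denominator, so swapping the arguments changes the
#' score exactly as when a 3-residue reference scored against a 2-residue
#' candidate gives 33% but the reverse comparison gives 50%. If the total
#' masses of the two sequences disagree beyond `mass_tolerance` the score
#' is 0 (with a warning): a candidate of the wrong mass is no
#' identification at all.
#'
#' @param reference the known `Peptide` (or string); its length is the
#'   denominator.
#' @param candidate the proposed `Peptide` (or string).
#' @param mass_tolerance amu tolerance on the boundary masses; default 0.01
#'   (candidates carry theoretical, not measured, masses).
#' @param collapse_il treat I and L as the same letter (they are isobaric);
#'   default `FALSE` - identity means letter identity.
#' @return object of class `MatchScore`: list with `n_matched`,
#'   `n_reference`, `percent`.
#' @examples
#' match_score("NC", "GGC")   # 50% (Asn mass = Gly + Gly)
#' @export
match_score <- function(reference, candidate, mass_tolerance = 0.01,
                        collapse_il = FALSE) {
  reference <- as_peptide(reference)
  candidate <- as_peptide(candidate)
  stopifnot(is.numeric(mass_tolerance), mass_tolerance >= 0)
  rr <- residues(reference)
  cr <- residues(candidate)
  if (collapse_il) {
    rr[rr == "I"] <- "L"
    cr[cr == "I"] <- "L"
  }
  ref_end <- prefix_masses(reference)
  ref_start <- c(0, ref_end[-length(ref_end)])
  cand_end <- prefix_masses(candidate)
  cand_start <- c(0, cand_end[-length(cand_end)])

  mk <- function(n_matched) {
    structure(list(n_matched = n_matched, n_reference = length(rr),
                   percent = 100 * n_matched / length(rr)),
              class = "MatchScore")
  }
  if (abs(ref_end[length(ref_end)] - cand_end[length(cand_end)]) >
      mass_tolerance) {
    warning("candidate total mass disagrees with the reference beyond tolerance; score 0")
    return(mk(0L))
  }
  used <- logical(length(rr))
  n_matched <- 0L
  for (i in seq_along(cr)) {
    j <- which(!used & rr == cr[i] &
                 abs(ref_start - cand_start[i]) <= mass_tolerance &
                 abs(ref_end - cand_end[i]) <= mass_tolerance)
    if (length(j) > 0) {
      used[j[1]] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  mk(n_matched)
}

#' @export
print.MatchScore <- function(x, ...) {
  cat(sprintf("MatchScore: %d of %d reference residues matched (%.1f%%)\n",
              x$n_matched, x$n_reference, x$percent))
  invisible(x)
}
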