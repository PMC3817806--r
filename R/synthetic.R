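# Ground-truth-labeled synthetic spectra: fragment peaks from a chosen
# peptide over a noise floor whose level varies across the m/z range - the
# regime a locally adaptive filter exists for.

#' Configuration for the synthetic spectrum generator
#'
#' Signal peaks are the peptide's theoretical ions, thinned by
#' `dropout_fraction`, jittered in m/z, with log-normal intensities whose
#' mean is `signal_intensity_mean` times the *local* noise-floor value
#' (secondary ions at `secondary_scale` of that). Noise peaks are uniform in m/z with
#' intensity equal to the local floor value times a bounded uniform
#' multiplier on `[0.4, 1.6]`: detector noise sits in a band around the
#' floor, bounded below by the instrument's reporting threshold and dense
#' at its top - the rank structure the SNR stopping rule relies on.
#'
#' @param pep a `Peptide` or sequence string (length >= 2).
#' @param signal_intensity_mean mean signal intensity as a multiple of the
#'   local noise floor; default 5. Fragment ions dominate their local
#'   neighborhoods, but when the floor varies several-fold across the
#'   spectrum a peak five times its local floor at low m/z can still sit
#'   below the raw noise band at high m/z - the situation a locally
#'   adaptive filter exists for.
#' @param signal_cv coefficient of variation of the log-normal signal
#'   intensities; default 1 (heavy-tailed: the weakest fragments sink into
#'   the noise band, the strongest stand an order of magnitude above it).
#' @param secondary_scale intensity of a/loss ions relative to b/y ions;
#'   default 0.15 - neutral-loss and a-ion peaks ride just above the local
#'   noise band, which is what makes them hard to keep.
#' @param noise_peak_count number of noise peaks; default 200.
#' @param noise_floor_profile one of `"constant"`, `"linear"`,
#'   `"quadratic"`, `"piecewise"` describing how the floor level moves
#'   across m/z.
#' @param floor_lo,floor_hi floor intensity at the low/high end of the m/z
#'   span; defaults 10 and 100 (a strongly rising floor).
#' @param floor_mid floor at mid-span for the quadratic profile; default
#'   `(floor_lo + floor_hi)/4` (a sag).
#' @param dropout_fraction probability that a theoretical ion is not
#'   observed, in `[0, 1)`; default 0.1.
#' @param mz_jitter_sd Gaussian m/z jitter on signal peaks, amu; default
#'   0.01.
#' @param seed integer RNG seed; the simulation is deterministic given it.
#' @param centroided centroided flag on the generated spectrum.
#' @param charge fragment charge; default 1.
#' @param include_losses generate water/ammonia loss ions; default `TRUE`.
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(pep,
                              signal_intensity_mean = 5,
                              signal_cv = 1,
                              secondary_scale = 0.15,
                              noise_peak_count = 200L,
                              noise_floor_profile = c("linear", "constant",
                                                      "quadratic", "piecewise"),
                              floor_lo = 10, floor_hi = 100,
                              floor_mid = NULL,
                              dropout_fraction = 0.1,
                              mz_jitter_sd = 0.01,
                              seed = 1L,
                              centroided = TRUE,
                              charge = 1L,
                              include_losses = TRUE) {
  pep <- as_peptide(pep)
  noise_floor_profile <- match.arg(noise_floor_profile)
  stopifnot(signal_intensity_mean > 0, signal_cv >= 0, secondary_scale > 0,
            noise_peak_count >= 0,
            dropout_fraction >= 0, dropout_fraction < 1,
            mz_jitter_sd >= 0, floor_lo >= 0, floor_hi >= 0)
  if (is.null(floor_mid)) floor_mid <- (floor_lo + floor_hi) / 4
  structure(
    list(pep = pep, signal_intensity_mean = signal_intensity_mean,
         signal_cv = signal_cv, secondary_scale = secondary_scale,
         noise_peak_count = as.integer(noise_peak_count),
         noise_floor_profile = noise_floor_profile,
         floor_lo = floor_lo, floor_hi = floor_hi, floor_mid = floor_mid,
         dropout_fraction = dropout_fraction, mz_jitter_sd = mz_jitter_sd,
         seed = as.integer(seed), centroided = isTRUE(centroided),
         charge = as.integer(charge), include_losses = isTRUE(include_losses)),
    class = "SimulationConfig"
  )
}

# Noise-floor level as a function of m/z over [lo, hi].
noise_floor_fun <- function(config, lo, hi) {
  fl <- config$floor_lo
  fh <- config$floor_hi
  switch(config$noise_floor_profile,
    constant = function(mz) rep(fl, length(mz)),
    linear = function(mz) fl + (fh - fl) * (mz - lo) / (hi - lo),
    quadratic = {
      # Lagrange parabola through (lo, fl), (mid, fm), (hi, fh)
      fm <- config$floor_mid
      mid <- (lo + hi) / 2
      function(mz) {
        fl * (mz - mid) * (mz - hi) / ((lo - mid) * (lo - hi)) +
          fm * (mz - lo) * (mz - hi) / ((mid - lo) * (mid - hi)) +
          fh * (mz - lo) * (mz - mid) / ((hi - lo) * (hi - mid))
      }
    },
    piecewise = {
      # four equal m/z segments stepping from floor_lo to floor_hi
      levels <- seq(fl, fh, length.out = 4)
      breaks <- seq(lo, hi, length.out = 5)
      function(mz) {
        seg <- pmin(pmax(findInterval(mz, breaks, rightmost.closed = TRUE), 1), 4)
        levels[seg]
      }
    }
  )
}

#' Simulate one ground-truth-labeled spectrum
#'
#' @param config a [simulation_config()].
#' @return list with `spectrum` (a `Spectrum`) and `truth` (data.frame:
#'   `mz`, `intensity`, `label`, `series`, `index`, `loss`, aligned row by
#'   row with the spectrum's peaks; attribute `floor` holds the noise-floor
#'   function used and `span` its m/z domain).
#' @examples
#' sim <- simulate_spectrum(simulation_config("SAMPLERK", seed = 42))
#' table(sim$truth$label)
#' @export
simulate_spectrum <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  ions <- theoretical_ions(config$pep, charge = config$charge,
                           include_losses = config$include_losses)
  withr::with_seed(config$seed, {
    lo <- min(ions$mz) - 30
    hi <- max(ions$mz) + 30
    floor_f <- noise_floor_fun(config, lo, hi)

    keep <- stats::runif(nrow(ions)) >= config$dropout_fraction
    ions_kept <- ions[keep, , drop = FALSE]
    ns <- nrow(ions_kept)
    sig <- NULL
    if (ns > 0) {
      mz_s <- ions_kept$mz +
        stats::rnorm(ns, 0, config$mz_jitter_sd)
      primary <- ions_kept$series %in% c("b", "y") & ions_kept$loss == "none"
      sdlog <- sqrt(log(1 + config$signal_cv^2))
      fac <- stats::rlnorm(ns, -sdlog^2 / 2, sdlog)
      scale <- ifelse(primary, 1, config$secondary_scale)
      int_s <- pmax(floor_f(mz_s), 1e-9) * config$signal_intensity_mean *
        scale * fac
      sig <- data.frame(mz = mz_s, intensity = int_s,
                        label = ifelse(primary, "primary", "secondary"),
                        series = ions_kept$series, index = ions_kept$index,
                        loss = ions_kept$loss)
    }
    noi <- NULL
    if (config$noise_peak_count > 0) {
      mz_n <- stats::runif(config$noise_peak_count, lo, hi)
      int_n <- pmax(floor_f(mz_n), 0) *
        stats::runif(config$noise_peak_count, 0.4, 1.6)
      noi <- data.frame(mz = mz_n, intensity = int_n, label = "noise",
                        series = NA_character_, index = NA_integer_,
                        loss = NA_character_)
    }
    all <- rbind(sig, noi)
    if (is.null(all) || nrow(all) == 0) stop("simulation produced no peaks")
    all <- all[order(all$mz), ]
    # collapse m/z collisions (< 1e-6 amu) the same way spectrum() would,
    # keeping the truth table aligned; signal label wins over noise
    grp <- cumsum(c(TRUE, diff(all$mz) > 1e-6))
    if (max(grp) < nrow(all)) {
      pick <- tapply(seq_len(nrow(all)), grp, function(ii) {
        s <- ii[all$label[ii] != "noise"]
        if (length(s)) s[1] else ii[1]
      })
      tot <- tapply(all$intensity, grp, sum)
      all <- all[as.integer(pick), ]
      all$intensity <- as.numeric(tot)
    }
    rownames(all) <- NULL
    sp <- spectrum(all$mz, all$intensity,
                   spectrum_id = sprintf("sim_%s_seed%d", unclass(config$pep),
                                         config$seed),
                   precursor_mz = (peptide_mass(config$pep) +
                                     MASS_CONST[["proton"]]),
                   precursor_charge = 1L,
                   centroided = config$centroided)
    truth <- all
    attr(truth, "floor") <- floor_f
    attr(truth, "span") <- c(lo, hi)
    list(spectrum = sp, truth = truth)
  })
}

#' Simulate a reproducible corpus of labeled spectra
#'
#' @param configs list of [simulation_config()] objects (the grid cells).
#' @param n_per_cell replicates per cell.
#' @param seed base seed; each replicate's seed is derived from it, the cell
#'   index and the replicate index.
#' @return list with `spectra` (list of `simulate_spectrum()` results) and
#'   `manifest` (data.frame: `spectrum_id`, `cell`, `replicate`, `seed`,
#'   `peptide`, `profile`).
#' @export
simulate_corpus <- function(configs, n_per_cell = 1L, seed = 1L) {
  if (!is.list(configs) || length(configs) == 0 ||
      !all(vapply(configs, inherits, logical(1), "SimulationConfig"))) {
    stop("configs must be a non-empty list of SimulationConfig objects",
         call. = FALSE)
  }
  spectra <- list()
  rows <- list()
  k <- 0L
  for (ci in seq_along(configs)) {
    for (ri in seq_len(n_per_cell)) {
      k <- k + 1L
      cfg <- configs[[ci]]
      cfg$seed <- as.integer((seed * 7919 + ci * 101 + ri) %% 2147483647L)
      sim <- simulate_spectrum(cfg)
      sim$spectrum$spectrum_id <- sprintf("cell%d_rep%d", ci, ri)
      spectra[[k]] <- sim
      rows[[k]] <- data.frame(spectrum_id = sim$spectrum$spectrum_id,
                              cell = ci, replicate = ri, seed = cfg$seed,
                              peptide = unclass(cfg$pep),
                              profile = cfg$noise_floor_profile)
    }
  }
  list(spectra = spectra, manifest = do.call(rbind, rows))
}

#' Build a LabeledSpectrum from simulation ground truth
#'
#' Wraps the generator's per-peak truth labels in the same container
#' [classify_peaks()] produces, so [retention_report()] and
#' [sweep_filters()] can consume either source of labels.
#'
#' @param sim a `simulate_spectrum()` result.
#' @return a `LabeledSpectrum`.
#' @export
labels_from_truth <- function(sim) {
  stopifnot(is.list(sim), inherits(sim$spectrum, "Spectrum"),
            is.data.frame(sim$truth))
  tr <- sim$truth
  lab <- data.frame(peak = seq_len(nrow(tr)), mz = tr$mz,
                    intensity = tr$intensity, label = tr$label,
                    series = tr$series, index = tr$index, loss = tr$loss)
  structure(list(spectrum = sim$spectrum, labels = lab,
                 peptide = NULL, tolerance = NA_real_),
            class = "LabeledSpectrum")
}
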