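## Synthetic-data module: breakdown-curve reference libraries, oral-fluid
## matrix background, spiked samples, dilution series, and a DDA
## acquisition simulator reproducing the instrument duty-cycle logic.
## Every generator is a pure function of (parameters, seed).

#' Synthetic analyte profile
#'
#' The ground-truth description of one simulated analyte: its compound
#' identity, a fragment template defining the collision-energy breakdown
#' curve, a Gaussian chromatographic peak, and a response factor linking
#' the spiked concentration (ng/mL in neat oral fluid) to the survey-scan
#' (MS1) intensity at the peak apex.
#'
#' @slot compound A [CompoundRecord-class].
#' @slot fragments Data frame with one row per fragment: `mz` (Th, below
#'   the precursor + 0.5), `appearanceCe` (eV at which the fragment first
#'   appears), `ceOpt` (eV of maximum yield) and `maxRel` (maximum relative
#'   intensity).
#' @slot rtApex Chromatographic peak apex (s).
#' @slot rtWidth Gaussian peak width sigma (s).
#' @slot responseFactor MS1 apex counts per ng/mL, > 0.
#'
#' @param compound,fragments,rtApex,rtWidth,responseFactor See slots.
#' @return An [AnalyteProfile-class] object.
#' @aliases AnalyteProfile-class
#' @export
AnalyteProfile <- function(compound, fragments, rtApex, rtWidth,
                           responseFactor) {
  new("AnalyteProfile", compound = compound, fragments = fragments,
      rtApex = rtApex, rtWidth = rtWidth, responseFactor = responseFactor)
}

setClass("AnalyteProfile",
  representation(compound = "CompoundRecord", fragments = "data.frame",
                 rtApex = "numeric", rtWidth = "numeric",
                 responseFactor = "numeric"))

setValidity("AnalyteProfile", function(object) {
  msgs <- character()
  need <- c("mz", "appearanceCe", "ceOpt", "maxRel")
  if (!all(need %in% names(object@fragments)))
    return(paste("fragments needs columns", paste(need, collapse = ", ")))
  if (any(object@fragments$mz >= object@compound@precursorMz + 0.5))
    msgs <- c(msgs, "fragment mz must be below precursor mz + 0.5")
  if (object@rtWidth <= 0 || object@responseFactor <= 0)
    msgs <- c(msgs, "rtWidth and responseFactor must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("compoundId", "AnalyteProfile", function(object, ...)
  object@compound@compoundId)
#' @rdname accessors
#' @export
setMethod("precursorMz", "AnalyteProfile", function(object, ...)
  object@compound@precursorMz)

setMethod("show", "AnalyteProfile", function(object) {
  cat(sprintf(
    "AnalyteProfile %s | [M+H]+ %.4f | %d fragments | rt %.0f±%.0f s | %.1f counts/(ng/mL)\n",
    object@compound@compoundId, object@compound@precursorMz,
    nrow(object@fragments), object@rtApex, object@rtWidth,
    object@responseFactor))
})

## Internal: noiseless fragment/precursor template at one collision energy.
## Fragment yield is a unimodal log-normal-shaped function of CE (zero
## before the appearance CE, maximum at ceOpt, decaying at high CE);
## precursor survival decays exponentially with CE.
templatePeaks <- function(profile, ce) {
  fr <- profile@fragments
  rel <- ifelse(ce < fr$appearanceCe, 0,
                fr$maxRel * exp(-(log(ce / fr$ceOpt))^2 / (2 * 0.45^2)))
  mzs <- c(fr$mz, profile@compound@precursorMz)
  ints <- c(rel, 100 * exp(-(ce - 5) / 12))
  keep <- ints > 1e-6
  list(mz = mzs[keep], intensity = 10 * ints[keep])
}

## Internal: acquisition-time template at nominal CE with spread, modelled
## as the average of the breakdown template over [ce - spread/2,
## ce + spread/2].
spreadTemplatePeaks <- function(profile, ce = 35, ceSpread = 10) {
  grid <- seq(ce - ceSpread / 2, ce + ceSpread / 2, length.out = 5)
  mzAll <- c(profile@fragments$mz, profile@compound@precursorMz)
  acc <- numeric(length(mzAll))
  for (g in grid) {
    fr <- profile@fragments
    rel <- ifelse(g < fr$appearanceCe, 0,
                  fr$maxRel * exp(-(log(g / fr$ceOpt))^2 / (2 * 0.45^2)))
    acc <- acc + c(rel, 100 * exp(-(g - 5) / 12))
  }
  ints <- 10 * acc / length(grid)
  keep <- ints > 1e-6
  list(mz = mzAll[keep], intensity = ints[keep])
}

#' Generate breakdown-curve reference spectra
#'
#' One noiseless product-ion spectrum per collision energy of `ceGrid`,
#' following the analyte's fragment template: each fragment rises after its
#' appearance CE, peaks at its optimum and falls at high CE, while the
#' surviving precursor decays with CE. Deterministic given `seed` (the seed
#' only matters when `noiseSigma > 0`).
#'
#' @param profile An [AnalyteProfile-class].
#' @param ceGrid Collision energies (eV); default the ten-step 5-50 eV
#'   acquisition grid.
#' @param seed Integer seed, or `NULL`.
#' @param noiseSigma Log-normal multiplicative intensity noise sigma
#'   (default 0, i.e. noiseless reference spectra).
#' @return List of MS2 [MassSpectrum-class], one per collision energy.
#' @export
generateBreakdownSpectra <- function(profile, ceGrid = seq(5, 50, by = 5),
                                     seed = NULL, noiseSigma = 0) {
  stopifnot(is(profile, "AnalyteProfile"), length(ceGrid) >= 1L)
  withSeed(seed, {
    lapply(ceGrid, function(ce) {
      tp <- templatePeaks(profile, ce)
      ints <- tp$intensity
      if (noiseSigma > 0)
        ints <- ints * exp(stats::rnorm(length(ints), 0, noiseSigma))
      MassSpectrum(mz = tp$mz, intensity = ints,
                   precursorMz = profile@compound@precursorMz,
                   rtime = profile@rtApex, collisionEnergy = ce,
                   msLevel = 2L,
                   scanId = sprintf("%s_ref_ce%g",
                                    profile@compound@compoundId, ce))
    })
  })
}

## Internal: one noisy acquisition-time MS2 spectrum for an analyte.
## Multiplicative log-normal intensity noise, Gaussian m/z jitter on
## fragments and precursor, scaled by `scale`, clipped to the MS/MS scan
## range.
acquisitionSpectrum <- function(profile, scale = 1, ce = 35, ceSpread = 10,
                                noiseSigma = 0.2, mzJitterSd = 0.002,
                                precursorJitterSd = 0.002,
                                msmsRange = c(50, 700), rtime = NA_real_,
                                scanId = "") {
  tp <- spreadTemplatePeaks(profile, ce, ceSpread)
  n <- length(tp$mz)
  ints <- scale * tp$intensity *
    if (noiseSigma > 0) exp(stats::rnorm(n, 0, noiseSigma)) else 1
  mzs <- tp$mz + if (mzJitterSd > 0) stats::rnorm(n, 0, mzJitterSd) else 0
  keep <- mzs >= msmsRange[1] & mzs <= msmsRange[2]
  pm <- profile@compound@precursorMz +
    if (precursorJitterSd > 0) stats::rnorm(1, 0, precursorJitterSd) else 0
  MassSpectrum(mz = mzs[keep], intensity = ints[keep], precursorMz = pm,
               rtime = rtime, collisionEnergy = ce, msLevel = 2L,
               scanId = scanId)
}

#' Generate noisy query spectra from an analyte profile
#'
#' Emulates acquisition-time product-ion spectra of an analyte: the
#' breakdown template averaged over the collision-energy spread (35 ± 5 eV
#' by default), with multiplicative log-normal intensity noise and Gaussian
#' m/z jitter on fragments and precursor. Used for sensitivity
#' (false-negative-rate) experiments.
#'
#' @param profile An [AnalyteProfile-class].
#' @param n Number of query spectra.
#' @param seed Integer seed.
#' @param ce,ceSpread Nominal collision energy and spread (eV).
#' @param noiseSigma Multiplicative log-normal noise sigma (default 0.2).
#' @param mzJitterSd Fragment m/z jitter sd in Th (default 0.002).
#' @param precursorJitterSd Precursor m/z jitter sd in Th (default 0.002).
#' @return List of `n` MS2 [MassSpectrum-class] objects.
#' @export
generateQuerySpectra <- function(profile, n = 10, seed = 1, ce = 35,
                                 ceSpread = 10, noiseSigma = 0.2,
                                 mzJitterSd = 0.002,
                                 precursorJitterSd = 0.002) {
  withSeed(seed, {
    lapply(seq_len(n), function(k)
      acquisitionSpectrum(profile, scale = 1, ce = ce, ceSpread = ceSpread,
                          noiseSigma = noiseSigma, mzJitterSd = mzJitterSd,
                          precursorJitterSd = precursorJitterSd,
                          scanId = sprintf("%s_query_%d",
                                           profile@compound@compoundId, k)))
  })
}

#' Generate a synthetic spectral library with ground-truth profiles
#'
#' Draws `nCompounds` analyte profiles (random precursor m/z, fragment
#' templates, logP values, chromatographic peaks and response factors),
#' renders their breakdown curves on `ceGrid` and curates them into a
#' [SpectralLibrary-class]. A configurable fraction of compounds is
#' generated isobaric (precursor m/z within 0.01 Th of another compound) to
#' stress the relative-score discrimination; all remaining precursor pairs
#' are kept more than 0.01 Th apart.
#'
#' @param nCompounds Number of library compounds (>= 1).
#' @param seed Integer seed.
#' @param precursorRange \[M+H\]+ m/z range (Th) within the survey scan
#'   range.
#' @param isobarFraction Fraction of compounds drawn as isobars of another
#'   compound, in \[0, 1\].
#' @param ceGrid Collision energies of the reference spectra (eV).
#' @param cutoffFactor Curation intensity cutoff.
#' @return A list with `library` (a [SpectralLibrary-class]) and `profiles`
#'   (named list of [AnalyteProfile-class], the ground truth).
#' @examples
#' gl <- generateLibrary(5, seed = 42)
#' libraryStats(gl$library)$nEntries
#' @export
generateLibrary <- function(nCompounds, seed = 1,
                            precursorRange = c(120, 650),
                            isobarFraction = 0, ceGrid = seq(5, 50, by = 5),
                            cutoffFactor = 0.01) {
  stopifnot(nCompounds >= 1, isobarFraction >= 0, isobarFraction <= 1)
  withSeed(seed, {
    nIso <- floor(isobarFraction * nCompounds / 2)
    nBase <- nCompounds - nIso
    precursors <- numeric(0)
    while (length(precursors) < nBase) {
      p <- stats::runif(1, precursorRange[1], precursorRange[2])
      if (!length(precursors) || min(abs(precursors - p)) > 0.02)
        precursors <- c(precursors, p)
    }
    if (nIso > 0) {
      partners <- sample(seq_len(nBase), nIso,
                         replace = nIso > nBase)
      precursors <- c(precursors,
                      precursors[partners] + stats::runif(nIso, -0.005, 0.005))
    }
    profiles <- vector("list", nCompounds)
    rtApex <- stats::runif(nCompounds, 30, 570)
    logp <- stats::rnorm(nCompounds, 2.8, 1.7)
    responseFactor <- 10^stats::runif(nCompounds, 0, log10(250))
    for (i in seq_len(nCompounds)) {
      id <- sprintf("CMP%04d", i)
      nFrag <- sample(6:12, 1)
      mzLo <- 60
      mzHi <- max(mzLo + 5, precursors[i] - 20)
      fmz <- numeric(0)
      while (length(fmz) < nFrag) {
        m <- stats::runif(1, mzLo, mzHi)
        if (!length(fmz) || min(abs(fmz - m)) > 0.05)
          fmz <- c(fmz, m)
      }
      fmz <- sort(fmz)
      appearance <- stats::runif(nFrag, 5, 28)
      ## guarantee low-CE fragments so the 30-40 eV acquisition window is
      ## always populated
      appearance[seq_len(min(3L, nFrag))] <- stats::runif(min(3L, nFrag),
                                                          5, 18)
      fragments <- data.frame(
        mz = fmz, appearanceCe = appearance, ceOpt = appearance + 10,
        maxRel = stats::runif(nFrag, 10, 100))
      compound <- CompoundRecord(
        compoundId = id, name = sprintf("analyte-%04d", i),
        precursorMz = precursors[i], logp = logp[i])
      profiles[[i]] <- AnalyteProfile(
        compound = compound, fragments = fragments, rtApex = rtApex[i],
        rtWidth = stats::runif(1, 6, 12), responseFactor = responseFactor[i])
    }
    names(profiles) <- vapply(profiles, compoundId, character(1))
    entries <- lapply(profiles, function(p)
      buildEntry(p@compound, generateBreakdownSpectra(p, ceGrid),
                 cutoffFactor = cutoffFactor))
    list(library = SpectralLibrary(entries = unname(entries),
                                   version = "synthetic"),
         profiles = profiles)
  })
}

#' Generate an oral-fluid matrix background model
#'
#' Draws `nPeaks` background ions with broad elution profiles (a constant
#' baseline fraction plus a wide Gaussian bump, so the matrix contributes
#' signal at all retention times, as oral fluid does). A configurable
#' fraction of ions is multiply charged (charge 2-3) and is represented in
#' survey scans by an isotope cluster with fractional spacing, emulating
#' the salivary peptidome. Background m/z values never fall within 0.01 Th
#' of any m/z in `avoidMzs` (typically the library precursors), unless that
#' overlap is requested by leaving `avoidMzs` empty.
#'
#' @param intensityScale Typical apex intensity (counts).
#' @param nPeaks Number of background ions (>= 0).
#' @param multiplyChargedFraction Fraction of ions with charge 2-3.
#' @param seed Integer seed.
#' @param avoidMzs m/z values the background must stay clear of (± 0.011).
#' @param duration Run duration (s) over which elution centres are drawn.
#' @param surveyRange Survey scan m/z range.
#' @return An object of class `"matrixBackground"`: a list with `ions`
#'   (data frame: `id`, `mz`, `charge`, `baseIntensity`, `rtCenter`,
#'   `rtWidth`) and `fragments` (per-ion MS2 fragment templates).
#' @export
generateMatrixBackground <- function(intensityScale = 500, nPeaks = 40,
                                     multiplyChargedFraction = 0.3,
                                     seed = 1, avoidMzs = numeric(0),
                                     duration = 600,
                                     surveyRange = c(100, 700)) {
  stopifnot(nPeaks >= 0)
  withSeed(seed, {
    drawMz <- function() {
      repeat {
        m <- stats::runif(1, surveyRange[1] + 1, surveyRange[2] - 3)
        if (!length(avoidMzs) || min(abs(avoidMzs - m)) > 0.011)
          return(m)
      }
    }
    charge <- rep(1L, nPeaks)
    if (nPeaks) {
      mc <- stats::runif(nPeaks) < multiplyChargedFraction
      charge[mc] <- sample(2:3, sum(mc), replace = TRUE)
    }
    ions <- data.frame(
      id = if (nPeaks) sprintf("BG%03d", seq_len(nPeaks)) else character(),
      mz = if (nPeaks) vapply(seq_len(nPeaks), function(i) drawMz(),
                              numeric(1)) else numeric(),
      charge = charge,
      baseIntensity = intensityScale *
        exp(stats::rnorm(nPeaks, 0, 0.5)),
      rtCenter = stats::runif(nPeaks, 0, duration),
      rtWidth = stats::runif(nPeaks, 60, 180),
      stringsAsFactors = FALSE)
    fragments <- lapply(seq_len(nPeaks), function(i) {
      nf <- sample(3:6, 1)
      data.frame(mz = sort(stats::runif(nf, 55, ions$mz[i])),
                 rel = stats::runif(nf, 10, 100))
    })
    names(fragments) <- ions$id
    structure(list(ions = ions, fragments = fragments,
                   duration = duration),
              class = "matrixBackground")
  })
}

## Internal: per-ion background intensity at time t (strictly positive:
## baseline fraction + broad Gaussian bump).
backgroundIntensityAt <- function(background, t) {
  ions <- background$ions
  if (!nrow(ions)) return(numeric(0))
  ions$baseIntensity *
    (0.15 + 0.85 * exp(-(t - ions$rtCenter)^2 / (2 * ions$rtWidth^2)))
}

#' Total background ion current at given times
#'
#' @param background A `"matrixBackground"`.
#' @param times Numeric vector of retention times (s).
#' @return Numeric vector: summed background intensity per time point.
#' @export
backgroundTic <- function(background, times) {
  vapply(times, function(t) sum(backgroundIntensityAt(background, t)),
         numeric(1))
}

#' Simulate a data-dependent acquisition run
#'
#' Reproduces the DDA duty cycle on synthetic analytes and matrix
#' background: per cycle one survey scan, then dependent MS/MS of the
#' `topN` most intense survey peaks that exceed the trigger threshold and
#' are not on the dynamic exclusion list; a precursor is excluded for
#' `exclusionWindow` seconds after `exclusionAfter` selections (the counter
#' resets when the window expires). Analyte MS2 spectra are drawn from the
#' breakdown template at the nominal collision energy with spread,
#' multiplicative noise and m/z jitter; matrix MS2 spectra come from the
#' background ions' fragment templates. Survey peaks are restricted to the
#' survey scan range and MS2 peaks to the MS/MS scan range.
#'
#' @param profiles List of [AnalyteProfile-class].
#' @param concentrations Numeric vector (ng/mL in neat oral fluid), one per
#'   profile; a concentration of 0 removes the analyte from the run.
#' @param background A `"matrixBackground"` or `NULL` for a clean run.
#' @param dda A [DdaParams-class].
#' @param duration Run duration (s), at least one duty cycle.
#' @param seed Integer seed.
#' @param noiseSigma,mzJitterSd,precursorJitterSd MS2 noise model, see
#'   [generateQuerySpectra()].
#' @return A list with `run` (the [MsRun-class]), `events` (data frame of
#'   selection events: `time`, `mz`, `intensity`, `source`, `scan_id`) and
#'   `detected` (character: analyte compound ids with at least one MS2
#'   spectrum).
#' @export
simulateDdaRun <- function(profiles, concentrations, background = NULL,
                           dda = DdaParams(), duration = 300, seed = 1,
                           noiseSigma = 0.2, mzJitterSd = 0.002,
                           precursorJitterSd = 0.002) {
  stopifnot(length(profiles) == length(concentrations),
            all(concentrations >= 0))
  cycleT <- ddaCycleTime(dda)
  if (duration < cycleT)
    stop("duration must cover at least one duty cycle (", cycleT, " s)")
  withSeed(seed, {
    cycles <- seq(0, duration, by = cycleT)
    exReg <- data.frame(mz = numeric(), count = integer(),
                        excludedUntil = numeric())
    spectraOut <- vector("list", 2L * length(cycles) * (1L + dda@topN))
    nOut <- 0L
    evTime <- numeric(); evMz <- numeric(); evInt <- numeric()
    evSource <- character(); evScan <- character()
    analyteIds <- vapply(profiles, compoundId, character(1))
    for (ci in seq_along(cycles)) {
      t <- cycles[ci]
      ## ---- survey scan ----------------------------------------------
      pmz <- numeric(); pint <- numeric(); psrc <- character()
      for (ai in seq_along(profiles)) {
        if (concentrations[ai] <= 0) next
        p <- profiles[[ai]]
        inten <- concentrations[ai] * p@responseFactor *
          exp(-(t - p@rtApex)^2 / (2 * p@rtWidth^2))
        if (inten >= 0.01) {
          pmz <- c(pmz, p@compound@precursorMz)
          pint <- c(pint, inten)
          psrc <- c(psrc, analyteIds[ai])
        }
      }
      if (!is.null(background) && nrow(background$ions)) {
        bint <- backgroundIntensityAt(background, t)
        for (bi in seq_len(nrow(background$ions))) {
          z <- background$ions$charge[bi]
          iso <- background$ions$mz[bi] + (0:2) * 1.00335 / z
          pmz <- c(pmz, iso)
          pint <- c(pint, bint[bi] * c(1, 0.7, 0.4))
          psrc <- c(psrc, rep(background$ions$id[bi], 3))
        }
      }
      inRange <- pmz >= dda@surveyRange[1] & pmz <= dda@surveyRange[2]
      pmz <- pmz[inRange]; pint <- pint[inRange]; psrc <- psrc[inRange]
      nOut <- nOut + 1L
      spectraOut[[nOut]] <- MassSpectrum(
        mz = pmz, intensity = pint, msLevel = 1L, rtime = t,
        scanId = sprintf("c%05d_ms1", ci))
      ## ---- precursor selection --------------------------------------
      if (!length(pmz)) next
      excluded <- vapply(pmz, function(m) {
        hit <- which(abs(exReg$mz - m) <= 0.01)
        any(hit) && any(t <= exReg$excludedUntil[hit] &
                        exReg$count[hit] >= dda@exclusionAfter)
      }, logical(1))
      ## reset expired exclusion counters
      expired <- exReg$count >= dda@exclusionAfter &
        exReg$excludedUntil < t
      if (any(expired)) exReg$count[expired] <- 0L
      eligible <- which(pint >= dda@triggerThreshold & !excluded)
      if (!length(eligible)) next
      sel <- eligible[order(-pint[eligible], pmz[eligible])]
      sel <- sel[seq_len(min(dda@topN, length(sel)))]
      for (k in seq_along(sel)) {
        i <- sel[k]
        scan <- sprintf("c%05d_ms2_%d", ci, k)
        evTime <- c(evTime, t); evMz <- c(evMz, pmz[i])
        evInt <- c(evInt, pint[i]); evSource <- c(evSource, psrc[i])
        evScan <- c(evScan, scan)
        ## exclusion bookkeeping
        hit <- which(abs(exReg$mz - pmz[i]) <= 0.01)
        if (length(hit)) {
          hit <- hit[1]
          exReg$count[hit] <- exReg$count[hit] + 1L
          if (exReg$count[hit] >= dda@exclusionAfter)
            exReg$excludedUntil[hit] <- t + dda@exclusionWindow
        } else {
          exReg <- rbind(exReg, data.frame(
            mz = pmz[i], count = 1L,
            excludedUntil = if (dda@exclusionAfter <= 1L)
              t + dda@exclusionWindow else -Inf))
        }
        ## dependent MS2 spectrum
        rtMs2 <- t + k * dda@accumulationTime
        ai <- match(psrc[i], analyteIds)
        nOut <- nOut + 1L
        if (!is.na(ai)) {
          spectraOut[[nOut]] <- acquisitionSpectrum(
            profiles[[ai]], scale = pint[i] / 100, ce = dda@ce,
            ceSpread = dda@ceSpread, noiseSigma = noiseSigma,
            mzJitterSd = mzJitterSd,
            precursorJitterSd = precursorJitterSd,
            msmsRange = dda@msmsRange, rtime = rtMs2, scanId = scan)
        } else {
          fr <- background$fragments[[psrc[i]]]
          keep <- fr$mz >= dda@msmsRange[1] & fr$mz <= dda@msmsRange[2]
          ints <- fr$rel[keep] * pint[i] / 100 *
            exp(stats::rnorm(sum(keep), 0, noiseSigma))
          spectraOut[[nOut]] <- MassSpectrum(
            mz = fr$mz[keep] + stats::rnorm(sum(keep), 0, mzJitterSd),
            intensity = ints, precursorMz = pmz[i], rtime = rtMs2,
            collisionEnergy = dda@ce, msLevel = 2L, scanId = scan)
        }
      }
    }
    events <- data.frame(time = evTime, mz = evMz, intensity = evInt,
                         source = evSource, scan_id = evScan,
                         stringsAsFactors = FALSE)
    run <- MsRun(spectra = spectraOut[seq_len(nOut)],
                 metadata = list(duration = duration, seed = seed,
                                 simulator = "dda"))
    list(run = run, events = events,
         detected = intersect(analyteIds, unique(events$source)))
  })
}

#' Generate a dilution-series experiment
#'
#' One simulated DDA run per concentration level of the standard series,
#' for a given extraction-solution volume of the collection device. Sample
#' preparation processes a fixed neat-oral-fluid-equivalent volume, so the
#' MS1 response scales with the concentration in neat oral fluid and the
#' extraction dilution factor cancels; the manifest still records the
#' in-vial concentration and the dilution factor. The per-level seeds are
#' derived from `seed` independently of the extraction volume, so two
#' volume variants with equal neat concentrations share their detection
#' ground truth.
#'
#' The manifest's `expected_detectable` flag is the generating-model ground
#' truth: whether the analyte's modelled survey intensity, sampled on the
#' duty-cycle time grid, reaches the trigger threshold at that level.
#'
#' @param profiles List of [AnalyteProfile-class]. Apexes are re-spaced
#'   `spacing` seconds apart so co-elution does not confound the series.
#' @param levels Concentration levels (ng/mL in neat oral fluid); default
#'   the standard seven-level series.
#' @param extractionVolume Extraction solution volume (µL), e.g. 400 or
#'   4000.
#' @param oralFluidVolume Collected oral fluid volume (µL), default 500.
#' @param seed Integer seed.
#' @param dda A [DdaParams-class].
#' @param spacing Apex spacing (s).
#' @param ... Passed to [simulateDdaRun()] (noise model).
#' @return A list with `runs` (named by level), `manifest` (data frame:
#'   `compound_id`, `level`, `in_vial`, `dilution_factor`,
#'   `expected_detectable`) and `profiles` (the re-spaced profiles).
#' @export
generateDilutionExperiment <- function(profiles,
                                       levels = c(1, 2.5, 5, 10, 25, 50, 100),
                                       extractionVolume = 400,
                                       oralFluidVolume = 500, seed = 1,
                                       dda = DdaParams(), spacing = 40,
                                       ...) {
  stopifnot(length(levels) >= 1L, all(levels > 0), oralFluidVolume > 0,
            extractionVolume >= 0)
  n <- length(profiles)
  for (i in seq_len(n)) profiles[[i]]@rtApex <- 30 + (i - 1) * spacing
  duration <- 60 + (n - 1) * spacing
  dilutionFactor <- (oralFluidVolume + extractionVolume) / oralFluidVolume
  cycleGrid <- seq(0, duration, by = ddaCycleTime(dda))
  runs <- vector("list", length(levels))
  manifest <- list()
  for (li in seq_along(levels)) {
    lev <- levels[li]
    childSeed <- (as.numeric(seed) * 1009 + li) %% 2147483647
    sim <- simulateDdaRun(profiles, rep(lev, n), background = NULL,
                          dda = dda, duration = duration, seed = childSeed,
                          ...)
    sim$run@metadata <- c(sim$run@metadata,
                          list(level = lev,
                               extraction_volume = extractionVolume,
                               dilution_factor = dilutionFactor))
    runs[[li]] <- sim
    expected <- vapply(profiles, function(p) {
      any(lev * p@responseFactor *
            exp(-(cycleGrid - p@rtApex)^2 / (2 * p@rtWidth^2)) >=
            dda@triggerThreshold)
    }, logical(1))
    manifest[[li]] <- data.frame(
      compound_id = vapply(profiles, compoundId, character(1)),
      level = lev, in_vial = lev / dilutionFactor,
      dilution_factor = dilutionFactor, expected_detectable = expected,
      stringsAsFactors = FALSE)
  }
  names(runs) <- as.character(levels)
  list(runs = runs, manifest = do.call(rbind, manifest),
       profiles = profiles)
}
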