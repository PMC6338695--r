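#' @import methods
NULL

## ---------------------------------------------------------------------------
## MassSpectrum
## ---------------------------------------------------------------------------

#' Centroided mass spectrum
#'
#' A single centroided (product-ion or survey) mass spectrum. Peaks are
#' stored sorted by ascending m/z; duplicate m/z values are merged by
#' intensity summation at construction time so that peak matching is well
#' defined downstream.
#'
#' @slot mz Numeric, peak m/z values (Th), strictly positive, sorted
#'   ascending, unique.
#' @slot intensity Numeric, peak abundances (counts), non-negative, same
#'   length as `mz`.
#' @slot precursorMz Precursor m/z (Th) for MS2 spectra, `NA` for MS1.
#' @slot rtime Retention time in seconds (>= 0, or `NA` if unknown).
#' @slot collisionEnergy Collision energy in eV (>= 0, or `NA`).
#' @slot msLevel Integer, 1 (survey) or 2 (product-ion).
#' @slot scanId Opaque scan identifier.
#'
#' @param mz,intensity Peak list vectors.
#' @param precursorMz,rtime,collisionEnergy,msLevel,scanId See slots.
#' @return `MassSpectrum()` returns a validated [MassSpectrum-class] object.
#' @examples
#' sp <- MassSpectrum(mz = c(91.05, 119.08), intensity = c(1000, 250),
#'                    precursorMz = 286.1438, collisionEnergy = 35)
#' peaksCount(sp)
#' @aliases MassSpectrum-class
#' @export
MassSpectrum <- function(mz, intensity, precursorMz = NA_real_,
                         rtime = NA_real_, collisionEnergy = NA_real_,
                         msLevel = 2L, scanId = "") {
  stopifnot(length(mz) == length(intensity))
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    ## merge exact duplicate centroids by intensity summation
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)),
                                     sum))
      mz <- unique(mz)
    }
  }
  new("MassSpectrum", mz = mz, intensity = intensity,
      precursorMz = as.numeric(precursorMz), rtime = as.numeric(rtime),
      collisionEnergy = as.numeric(collisionEnergy),
      msLevel = as.integer(msLevel), scanId = as.character(scanId))
}

setClass("MassSpectrum",
  representation(mz = "numeric", intensity = "numeric",
                 precursorMz = "numeric", rtime = "numeric",
                 collisionEnergy = "numeric", msLevel = "integer",
                 scanId = "character"),
  prototype(mz = numeric(), intensity = numeric(), precursorMz = NA_real_,
            rtime = NA_real_, collisionEnergy = NA_real_, msLevel = 2L,
            scanId = ""))

setValidity("MassSpectrum", function(object) {
  msgs <- character()
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (length(object@mz)) {
    if (any(!is.finite(object@mz)) || any(object@mz <= 0))
      msgs <- c(msgs, "all mz values must be finite and > 0")
    if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
      msgs <- c(msgs, "all intensities must be finite and >= 0")
    if (is.unsorted(object@mz, strictly = TRUE))
      msgs <- c(msgs, "peaks must be strictly sorted by ascending mz")
  }
  if (!object@msLevel %in% c(1L, 2L))
    msgs <- c(msgs, "msLevel must be 1 or 2")
  if (!is.na(object@rtime) && object@rtime < 0)
    msgs <- c(msgs, "rtime must be >= 0")
  if (!is.na(object@collisionEnergy) && object@collisionEnergy < 0)
    msgs <- c(msgs, "collisionEnergy must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("mz", "MassSpectrum", function(object, ...) object@mz)
#' @rdname accessors
#' @export
setMethod("intensity", "MassSpectrum", function(object, ...) object@intensity)
#' @rdname accessors
#' @export
setMethod("peaksCount", "MassSpectrum", function(object, ...)
  length(object@mz))
#' @rdname accessors
#' @export
setMethod("precursorMz", "MassSpectrum", function(object, ...)
  object@precursorMz)
#' @rdname accessors
#' @export
setMethod("rtime", "MassSpectrum", function(object, ...) object@rtime)
#' @rdname accessors
#' @export
setMethod("collisionEnergy", "MassSpectrum", function(object, ...)
  object@collisionEnergy)
#' @rdname accessors
#' @export
setMethod("msLevel", "MassSpectrum", function(object, ...) object@msLevel)
#' @rdname accessors
#' @export
setMethod("scanId", "MassSpectrum", function(object, ...) object@scanId)

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum (MS%d) | %d peak%s", object@msLevel,
              length(object@mz), if (length(object@mz) == 1) "" else "s"))
  if (!is.na(object@precursorMz))
    cat(sprintf(" | precursor m/z %.4f", object@precursorMz))
  if (!is.na(object@collisionEnergy))
    cat(sprintf(" | CE %g eV", object@collisionEnergy))
  if (!is.na(object@rtime))
    cat(sprintf(" | rt %.1f s", object@rtime))
  cat("\n")
})

## ---------------------------------------------------------------------------
## MsRun
## ---------------------------------------------------------------------------

#' An acquisition run
#'
#' A time-ordered collection of [MassSpectrum-class] objects with free-form
#' metadata (sample id, dilution factor, ...). Retention times must be
#' non-decreasing over the non-missing subsequence.
#'
#' @slot spectra List of [MassSpectrum-class] objects.
#' @slot metadata Named list of free-form metadata.
#'
#' @param spectra,metadata See slots.
#' @return `MsRun()` returns a validated [MsRun-class] object.
#' @aliases MsRun-class
#' @export
MsRun <- function(spectra = list(), metadata = list()) {
  new("MsRun", spectra = spectra, metadata = metadata)
}

setClass("MsRun",
  representation(spectra = "list", metadata = "list"),
  prototype(spectra = list(), metadata = list()))

setValidity("MsRun", function(object) {
  msgs <- character()
  if (length(object@spectra) &&
      !all(vapply(object@spectra, is, logical(1), "MassSpectrum")))
    msgs <- c(msgs, "all elements of spectra must be MassSpectrum objects")
  rts <- vapply(object@spectra, function(s) s@rtime, numeric(1))
  rts <- rts[!is.na(rts)]
  if (length(rts) > 1 && is.unsorted(rts))
    msgs <- c(msgs, "retention times must be non-decreasing across spectra")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("spectra", "MsRun", function(object, ...) object@spectra)
#' @rdname accessors
#' @export
setMethod("runMetadata", "MsRun", function(object, ...) object@metadata)
#' @export
setMethod("length", "MsRun", function(x) length(x@spectra))

setMethod("show", "MsRun", function(object) {
  lv <- vapply(object@spectra, function(s) s@msLevel, integer(1))
  cat(sprintf("MsRun | %d spectra (%d MS1, %d MS2)\n", length(lv),
              sum(lv == 1L), sum(lv == 2L)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Extract the MS2 spectra of a run
#'
#' @param run An [MsRun-class].
#' @return List of the product-ion ([MassSpectrum-class], `msLevel == 2`)
#'   spectra in acquisition order.
#' @export
ms2Spectra <- function(run) {
  stopifnot(is(run, "MsRun"))
  Filter(function(s) msLevel(s) == 2L, spectra(run))
}

## ---------------------------------------------------------------------------
## CompoundRecord / LibraryEntry / SpectralLibrary
## ---------------------------------------------------------------------------

#' Compound identity record
#'
#' Identity metadata for one library compound: name, monoisotopic \[M+H\]+
#' m/z and the octanol-water partition coefficient (logP) used for the
#' applicability-window analysis. logP may be `NA` when unknown.
#'
#' @slot compoundId Unique compound identifier within a library.
#' @slot name Human-readable compound name.
#' @slot precursorMz \[M+H\]+ m/z (Th), > 0.
#' @slot logp Octanol-water partition coefficient (dimensionless) or `NA`.
#'
#' @param compoundId,name,precursorMz,logp See slots.
#' @return A [CompoundRecord-class] object.
#' @aliases CompoundRecord-class
#' @export
CompoundRecord <- function(compoundId, name = compoundId, precursorMz,
                           logp = NA_real_) {
  new("CompoundRecord", compoundId = as.character(compoundId),
      name = as.character(name), precursorMz = as.numeric(precursorMz),
      logp = as.numeric(logp))
}

setClass("CompoundRecord",
  representation(compoundId = "character", name = "character",
                 precursorMz = "numeric", logp = "numeric"))

setValidity("CompoundRecord", function(object) {
  msgs <- character()
  if (!nzchar(object@compoundId))
    msgs <- c(msgs, "compoundId must be non-empty")
  if (!is.finite(object@precursorMz) || object@precursorMz <= 0)
    msgs <- c(msgs, "precursorMz must be finite and > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("compoundId", "CompoundRecord", function(object, ...)
  object@compoundId)
#' @rdname accessors
#' @export
setMethod("compoundName", "CompoundRecord", function(object, ...) object@name)
#' @rdname accessors
#' @export
setMethod("precursorMz", "CompoundRecord", function(object, ...)
  object@precursorMz)
#' @rdname accessors
#' @export
setMethod("logP", "CompoundRecord", function(object, ...) object@logp)

setMethod("show", "CompoundRecord", function(object) {
  cat(sprintf("CompoundRecord %s (%s) | [M+H]+ %.4f | logP %s\n",
              object@compoundId, object@name, object@precursorMz,
              if (is.na(object@logp)) "NA" else format(object@logp)))
})

#' Library entry: one compound and its reference spectra
#'
#' One compound together with its curated product-ion reference spectra at
#' distinct collision energies. The multi-collision-energy set covers the
#' compound-specific breakdown curve; collision energies lie in \[5, 50\] eV
#' and every reference spectrum's precursor agrees with the compound's
#' \[M+H\]+ m/z within 0.01 Th.
#'
#' @slot compound A [CompoundRecord-class].
#' @slot spectra List of [MassSpectrum-class] sorted by collision energy.
#'
#' @param compound,spectra See slots.
#' @return A [LibraryEntry-class] object.
#' @aliases LibraryEntry-class
#' @export
LibraryEntry <- function(compound, spectra) {
  ce <- vapply(spectra, collisionEnergy, numeric(1))
  new("LibraryEntry", compound = compound, spectra = spectra[order(ce)])
}

setClass("LibraryEntry",
  representation(compound = "CompoundRecord", spectra = "list"))

setValidity("LibraryEntry", function(object) {
  msgs <- character()
  if (!length(object@spectra))
    msgs <- c(msgs, "an entry needs at least one reference spectrum")
  else {
    if (!all(vapply(object@spectra, is, logical(1), "MassSpectrum")))
      return("all reference spectra must be MassSpectrum objects")
    ce <- vapply(object@spectra, collisionEnergy, numeric(1))
    pm <- vapply(object@spectra, precursorMz, numeric(1))
    if (anyNA(ce) || anyDuplicated(ce))
      msgs <- c(msgs, "reference spectra must have distinct collision energies")
    if (any(!is.na(ce) & (ce < 5 | ce > 50)))
      msgs <- c(msgs, "collision energies must lie in [5, 50] eV")
    if (any(is.na(pm) | abs(pm - object@compound@precursorMz) > 0.01))
      msgs <- c(msgs,
        "all reference spectra must share the compound precursor m/z within 0.01")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("compoundId", "LibraryEntry", function(object, ...)
  object@compound@compoundId)
#' @rdname accessors
#' @export
setMethod("compoundName", "LibraryEntry", function(object, ...)
  object@compound@name)
#' @rdname accessors
#' @export
setMethod("precursorMz", "LibraryEntry", function(object, ...)
  object@compound@precursorMz)
#' @rdname accessors
#' @export
setMethod("logP", "LibraryEntry", function(object, ...) object@compound@logp)
#' @rdname accessors
#' @export
setMethod("referenceSpectra", "LibraryEntry", function(object, ...)
  object@spectra)
#' @export
setMethod("length", "LibraryEntry", function(x) length(x@spectra))

setMethod("show", "LibraryEntry", function(object) {
  ce <- vapply(object@spectra, collisionEnergy, numeric(1))
  cat(sprintf("LibraryEntry %s | %d reference spectra | CE %s eV\n",
              object@compound@compoundId, length(object@spectra),
              paste(ce, collapse = ",")))
})

#' Multi-collision-energy tandem mass spectral library
#'
#' An ordered collection of [LibraryEntry-class] objects with unique
#' compound ids.
#'
#' @slot entries List of [LibraryEntry-class].
#' @slot version Free-form version string.
#'
#' @param entries,version See slots.
#' @return A [SpectralLibrary-class] object.
#' @aliases SpectralLibrary-class
#' @export
SpectralLibrary <- function(entries = list(), version = "0") {
  new("SpectralLibrary", entries = entries, version = as.character(version))
}

setClass("SpectralLibrary",
  representation(entries = "list", version = "character"),
  prototype(entries = list(), version = "0"))

setValidity("SpectralLibrary", function(object) {
  msgs <- character()
  if (length(object@entries)) {
    if (!all(vapply(object@entries, is, logical(1), "LibraryEntry")))
      return("all entries must be LibraryEntry objects")
    ids <- vapply(object@entries, compoundId, character(1))
    if (anyDuplicated(ids))
      msgs <- c(msgs, "compound ids must be unique within a library")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("entries", "SpectralLibrary", function(object, ...) object@entries)
#' @rdname accessors
#' @export
setMethod("compoundIds", "SpectralLibrary", function(object, ...)
  vapply(object@entries, compoundId, character(1)))
#' @export
setMethod("length", "SpectralLibrary", function(x) length(x@entries))

setMethod("show", "SpectralLibrary", function(object) {
  ns <- sum(vapply(object@entries, length, integer(1)))
  cat(sprintf("SpectralLibrary v%s | %d entries | %d spectra\n",
              object@version, length(object@entries), ns))
})

## ---------------------------------------------------------------------------
## SearchParams
## ---------------------------------------------------------------------------

#' Library-search parameters
#'
#' Tolerances, the intensity cutoff and the positive-identification
#' thresholds of the search engine. Defaults are the screening settings:
#' precursor and fragment m/z tolerance 0.01 Th, intensity cutoff factor
#' 0.01 of the base peak, and the strict amp > 5.0 / ramp > 40.0 decision
#' rule.
#'
#' @slot precursorTol Precursor m/z tolerance (Th), absolute.
#' @slot mzMatchTol Fragment m/z match tolerance (Th), absolute.
#' @slot intensityCutoffFactor Fraction of the base-peak intensity below
#'   which peaks are discarded before matching, in \[0, 1).
#' @slot ampThreshold Average match probability threshold (strict >).
#' @slot rampThreshold Relative average match probability threshold
#'   (strict >).
#'
#' @param precursorTol,mzMatchTol,intensityCutoffFactor See slots.
#' @param ampThreshold,rampThreshold See slots.
#' @return A [SearchParams-class] object.
#' @examples
#' SearchParams()
#' @aliases SearchParams-class
#' @export
SearchParams <- function(precursorTol = 0.01, mzMatchTol = 0.01,
                         intensityCutoffFactor = 0.01, ampThreshold = 5.0,
                         rampThreshold = 40.0) {
  new("SearchParams", precursorTol = precursorTol, mzMatchTol = mzMatchTol,
      intensityCutoffFactor = intensityCutoffFactor,
      ampThreshold = ampThreshold, rampThreshold = rampThreshold)
}

setClass("SearchParams",
  representation(precursorTol = "numeric", mzMatchTol = "numeric",
                 intensityCutoffFactor = "numeric", ampThreshold = "numeric",
                 rampThreshold = "numeric"))

setValidity("SearchParams", function(object) {
  msgs <- character()
  if (object@precursorTol <= 0 || object@mzMatchTol <= 0)
    msgs <- c(msgs, "tolerances must be > 0")
  if (object@intensityCutoffFactor < 0 || object@intensityCutoffFactor >= 1)
    msgs <- c(msgs, "intensityCutoffFactor must be in [0, 1)")
  if (object@ampThreshold < 0 || object@ampThreshold > 100 ||
      object@rampThreshold < 0 || object@rampThreshold > 100)
    msgs <- c(msgs, "score thresholds must be in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SearchParams", function(object) {
  cat(sprintf(paste0(
    "SearchParams | precursor tol ±%g Th | mz tol ±%g Th | ",
    "cutoff %g | amp > %g & ramp > %g\n"),
    object@precursorTol, object@mzMatchTol, object@intensityCutoffFactor,
    object@ampThreshold, object@rampThreshold))
})

## ---------------------------------------------------------------------------
## DdaParams
## ---------------------------------------------------------------------------

#' Data-dependent acquisition parameters
#'
#' The DDA duty cycle contract of the simulated QqTOF instrument: one survey
#' MS scan followed by up to `topN` dependent MS/MS scans of the most
#' intense precursors above `triggerThreshold` counts; a precursor is put on
#' the dynamic exclusion list for `exclusionWindow` seconds after
#' `exclusionAfter` selections. Survey scans cover m/z 100-700, product-ion
#' scans m/z 50-700; MS/MS is acquired at 35 eV with a 10 eV collision
#' energy spread. The cycle time is `(1 + topN) * accumulationTime`
#' (100 ms per scan) plus a fixed overhead.
#'
#' @slot topN Maximum dependent MS/MS scans per cycle.
#' @slot triggerThreshold Survey intensity (counts) required to trigger
#'   MS/MS.
#' @slot exclusionAfter Number of selections after which a precursor is
#'   excluded.
#' @slot exclusionWindow Exclusion duration (s).
#' @slot surveyRange,msmsRange Scan ranges (m/z, length-2).
#' @slot ce Nominal collision energy (eV).
#' @slot ceSpread Collision energy spread (eV).
#' @slot accumulationTime Per-scan accumulation time (s).
#' @slot cycleOverhead Fixed per-cycle overhead (s).
#'
#' @param topN,triggerThreshold,exclusionAfter,exclusionWindow See slots.
#' @param surveyRange,msmsRange,ce,ceSpread See slots.
#' @param accumulationTime,cycleOverhead See slots.
#' @return A [DdaParams-class] object.
#' @examples
#' ddaCycleTime(DdaParams())
#' @aliases DdaParams-class
#' @export
DdaParams <- function(topN = 8L, triggerThreshold = 100,
                      exclusionAfter = 2L, exclusionWindow = 30,
                      surveyRange = c(100, 700), msmsRange = c(50, 700),
                      ce = 35, ceSpread = 10, accumulationTime = 0.1,
                      cycleOverhead = 0.05) {
  new("DdaParams", topN = as.integer(topN),
      triggerThreshold = triggerThreshold,
      exclusionAfter = as.integer(exclusionAfter),
      exclusionWindow = exclusionWindow, surveyRange = surveyRange,
      msmsRange = msmsRange, ce = ce, ceSpread = ceSpread,
      accumulationTime = accumulationTime, cycleOverhead = cycleOverhead)
}

setClass("DdaParams",
  representation(topN = "integer", triggerThreshold = "numeric",
                 exclusionAfter = "integer", exclusionWindow = "numeric",
                 surveyRange = "numeric", msmsRange = "numeric",
                 ce = "numeric", ceSpread = "numeric",
                 accumulationTime = "numeric", cycleOverhead = "numeric"))

setValidity("DdaParams", function(object) {
  msgs <- character()
  if (object@topN < 1L) msgs <- c(msgs, "topN must be >= 1")
  if (object@triggerThreshold <= 0 || object@exclusionWindow <= 0 ||
      object@exclusionAfter < 1L)
    msgs <- c(msgs, "thresholds must be positive")
  if (length(object@surveyRange) != 2L || length(object@msmsRange) != 2L)
    msgs <- c(msgs, "scan ranges must be length-2 (min, max)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname DdaParams
#' @param params A [DdaParams-class] object.
#' @export
ddaCycleTime <- function(params) {
  (1 + params@topN) * params@accumulationTime + params@cycleOverhead
}

setMethod("show", "DdaParams", function(object) {
  cat(sprintf(paste0(
    "DdaParams | top %d | trigger %g counts | exclusion %g s after %d | ",
    "cycle %.2f s\n"), object@topN, object@triggerThreshold,
    object@exclusionWindow, object@exclusionAfter, ddaCycleTime(object)))
})
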