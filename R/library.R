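## Reference-library curation, construction, MSP-like persistence and
## summary statistics.

#' Curate a reference spectrum
#'
#' Two-stage curation of a product-ion spectrum for library inclusion:
#' first low-abundance peaks are dropped relative to the base peak
#' ([applyIntensityCutoff()]), then peaks within `mzTol` of any known
#' unspecific m/z (solvent clusters, background ions) are removed. The base
#' peak is only ever removed by the second stage, i.e. when it is itself an
#' unspecific signal. Curation is idempotent and order-stable.
#'
#' @param spectrum A [MassSpectrum-class] with `msLevel == 2`.
#' @param cutoffFactor Relative intensity cutoff in \[0, 1); default 0.01.
#' @param noiseMzs Numeric vector of known-unspecific m/z values; default
#'   empty.
#' @param mzTol Absolute m/z tolerance (Th) for the exclusion list; default
#'   0.01.
#' @return The curated [MassSpectrum-class].
#' @export
curateSpectrum <- function(spectrum, cutoffFactor = 0.01,
                           noiseMzs = numeric(0), mzTol = 0.01) {
  stopifnot(is(spectrum, "MassSpectrum"))
  if (msLevel(spectrum) != 2L)
    stop("curateSpectrum expects a product-ion (MS2) spectrum")
  out <- applyIntensityCutoff(spectrum, cutoffFactor)
  if (length(noiseMzs) && peaksCount(out)) {
    noisy <- vapply(out@mz, function(m) any(abs(m - noiseMzs) <= mzTol),
                    logical(1))
    out <- initialize(out, mz = out@mz[!noisy],
                      intensity = out@intensity[!noisy])
  }
  out
}

#' Build a library entry from raw reference spectra
#'
#' Curates a set of product-ion spectra acquired at distinct collision
#' energies (the compound's breakdown curve) and assembles them, sorted by
#' collision energy, into a [LibraryEntry-class]. Every raw spectrum's
#' precursor must agree with the compound's \[M+H\]+ m/z within 0.01 Th.
#'
#' @param compound A [CompoundRecord-class].
#' @param rawSpectra List of MS2 [MassSpectrum-class] objects at distinct
#'   collision energies.
#' @param cutoffFactor,noiseMzs,mzTol Curation parameters, see
#'   [curateSpectrum()].
#' @return A [LibraryEntry-class].
#' @export
buildEntry <- function(compound, rawSpectra, cutoffFactor = 0.01,
                       noiseMzs = numeric(0), mzTol = 0.01) {
  stopifnot(is(compound, "CompoundRecord"), length(rawSpectra) >= 1L)
  pm <- vapply(rawSpectra, precursorMz, numeric(1))
  off <- which(is.na(pm) | abs(pm - precursorMz(compound)) > 0.01)
  if (length(off))
    stop("precursor mismatch for compound ", compoundId(compound),
         ": spectrum ", off[1], " (scan '", scanId(rawSpectra[[off[1]]]),
         "') has precursor ", pm[off[1]], ", expected ",
         precursorMz(compound), " ± 0.01")
  ce <- vapply(rawSpectra, collisionEnergy, numeric(1))
  if (anyNA(ce) || anyDuplicated(ce))
    stop("reference spectra for ", compoundId(compound),
         " must carry distinct collision energies")
  curated <- lapply(rawSpectra, curateSpectrum, cutoffFactor = cutoffFactor,
                    noiseMzs = noiseMzs, mzTol = mzTol)
  LibraryEntry(compound = compound, spectra = curated)
}

#' Read / write an MSP-like spectral library
#'
#' The library is persisted as MSP-like plain text: one record per
#' reference spectrum, records of the same `CompoundID` grouped into one
#' entry. Each record carries `Name`, `CompoundID`, `PrecursorMZ`
#' (mandatory), optional `LogP`, `CollisionEnergy`, then
#' `Num Peaks: <n>` and `n` peak lines (`mz intensity`). Records are
#' separated by blank lines. A write/read round trip is an identity on the
#' data model to six decimal places.
#'
#' @param path File path.
#' @return `readMsp()` returns a [SpectralLibrary-class].
#' @export
readMsp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[[i]]))) {
      i <- i + 1L
      next
    }
    fields <- list()
    while (i <= n && grepl("^[A-Za-z][A-Za-z ]*:", lines[[i]])) {
      key <- trimws(sub(":.*$", "", lines[[i]]))
      val <- trimws(sub("^[^:]*:", "", lines[[i]]))
      fields[[key]] <- val
      i <- i + 1L
    }
    if (is.null(fields[["Num Peaks"]]))
      stop("MSP parse error near line ", i, ": record without 'Num Peaks'")
    if (is.null(fields[["PrecursorMZ"]]))
      stop("MSP parse error near line ", i, ": record missing PrecursorMZ")
    np <- as.integer(fields[["Num Peaks"]])
    mzs <- numeric(np)
    ints <- numeric(np)
    for (k in seq_len(np)) {
      if (i > n || !nzchar(trimws(lines[[i]])))
        stop("MSP parse error near line ", i, ": expected ", np,
             " peak lines, found ", k - 1L)
      pk <- suppressWarnings(as.numeric(strsplit(trimws(lines[[i]]),
                                                 "[ \t]+")[[1]][1:2]))
      if (anyNA(pk))
        stop("MSP parse error at line ", i, ": bad peak line")
      mzs[k] <- pk[1]
      ints[k] <- pk[2]
      i <- i + 1L
    }
    if (i <= n && nzchar(trimws(lines[[i]])) &&
        !grepl("^[A-Za-z][A-Za-z ]*:", lines[[i]]))
      stop("MSP parse error at line ", i, ": more peak lines than 'Num Peaks'")
    records[[length(records) + 1L]] <- list(fields = fields, mz = mzs,
                                            intensity = ints)
  }
  entryIds <- unique(vapply(records, function(r)
    r$fields[["CompoundID"]] %||% r$fields[["Name"]], character(1)))
  entries <- lapply(entryIds, function(id) {
    recs <- Filter(function(r)
      (r$fields[["CompoundID"]] %||% r$fields[["Name"]]) == id, records)
    f1 <- recs[[1]]$fields
    logp <- if (is.null(f1[["LogP"]])) NA_real_ else as.numeric(f1[["LogP"]])
    compound <- CompoundRecord(
      compoundId = id, name = f1[["Name"]] %||% id,
      precursorMz = as.numeric(f1[["PrecursorMZ"]]), logp = logp)
    sps <- lapply(recs, function(r)
      MassSpectrum(mz = r$mz, intensity = r$intensity,
                   precursorMz = as.numeric(r$fields[["PrecursorMZ"]]),
                   collisionEnergy =
                     if (is.null(r$fields[["CollisionEnergy"]])) NA_real_
                     else as.numeric(r$fields[["CollisionEnergy"]]),
                   msLevel = 2L,
                   scanId = sprintf("%s_ce%s", id,
                                    r$fields[["CollisionEnergy"]] %||% "NA")))
    LibraryEntry(compound = compound, spectra = sps)
  })
  SpectralLibrary(entries = entries, version = "imported")
}

#' @rdname readMsp
#' @param library A [SpectralLibrary-class].
#' @return `writeMsp()` returns `path`, invisibly.
#' @export
writeMsp <- function(library, path) {
  stopifnot(is(library, "SpectralLibrary"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (entry in entries(library)) {
    cmp <- entry@compound
    for (sp in referenceSpectra(entry)) {
      writeLines(c(
        paste0("Name: ", compoundName(cmp)),
        paste0("CompoundID: ", compoundId(cmp)),
        sprintf("PrecursorMZ: %.6f", precursorMz(cmp))), con)
      if (!is.na(logP(cmp)))
        writeLines(sprintf("LogP: %g", logP(cmp)), con)
      if (!is.na(collisionEnergy(sp)))
        writeLines(sprintf("CollisionEnergy: %g", collisionEnergy(sp)), con)
      writeLines(sprintf("Num Peaks: %d", peaksCount(sp)), con)
      if (peaksCount(sp))
        writeLines(sprintf("%.6f %.6f", mz(sp), intensity(sp)), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary statistics of a spectral library
#'
#' @param library A [SpectralLibrary-class].
#' @return A list with `nEntries`, `nSpectra`, `ceHistogram` (table of
#'   spectra per collision energy), `nWithLogp` and `logpRange`.
#' @examples
#' libraryStats(SpectralLibrary())
#' @export
libraryStats <- function(library) {
  stopifnot(is(library, "SpectralLibrary"))
  ents <- entries(library)
  perEntry <- vapply(ents, length, integer(1))
  ces <- unlist(lapply(ents, function(e)
    vapply(referenceSpectra(e), collisionEnergy, numeric(1))))
  logps <- vapply(ents, logP, numeric(1))
  list(
    nEntries = length(ents),
    nSpectra = sum(perEntry),
    ceHistogram = if (length(ces)) table(ces) else table(numeric(0)),
    nWithLogp = sum(!is.na(logps)),
    logpRange = if (any(!is.na(logps))) range(logps, na.rm = TRUE)
                else c(NA_real_, NA_real_))
}
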