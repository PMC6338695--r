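## The identification engine: candidate filtering on the precursor, the
## matched-peak similarity kernel, compound-level amp/ramp scoring and the
## positive-identification decision rule.

#' Filter library entries by precursor m/z
#'
#' Returns exactly the entries whose \[M+H\]+ m/z lies within
#' `precursorTol` (absolute, Th) of the query's precursor, in library
#' order. Isobaric entries are all returned; disambiguation is left to the
#' relative (ramp) score.
#'
#' @param query An MS2 [MassSpectrum-class].
#' @param library A [SpectralLibrary-class].
#' @param precursorTol Absolute precursor tolerance in Th (default 0.01).
#' @return List of [LibraryEntry-class] (possibly empty).
#' @export
candidateFilter <- function(query, library, precursorTol = 0.01) {
  stopifnot(is(query, "MassSpectrum"), is(library, "SpectralLibrary"))
  if (msLevel(query) != 2L)
    stop("candidateFilter expects a product-ion (MS2) query")
  pm <- precursorMz(query)
  if (is.na(pm)) return(list())
  Filter(function(e) abs(precursorMz(e) - pm) <= precursorTol,
         entries(library))
}

## Internal: greedy one-to-one peak matching by smallest |delta mz| within
## tol; ties broken by lower query mz, then lower reference mz, for
## determinism. Returns a two-column index matrix (query, reference).
matchPeaks <- function(qmz, rmz, tol) {
  if (!length(qmz) || !length(rmz))
    return(matrix(integer(), ncol = 2))
  d <- abs(outer(qmz, rmz, "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (!nrow(cand))
    return(matrix(integer(), ncol = 2))
  o <- order(d[cand], qmz[cand[, 1]], rmz[cand[, 2]])
  cand <- cand[o, , drop = FALSE]
  usedQ <- logical(length(qmz))
  usedR <- logical(length(rmz))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    qi <- cand[k, 1]
    ri <- cand[k, 2]
    if (!usedQ[qi] && !usedR[ri]) {
      usedQ[qi] <- TRUE
      usedR[ri] <- TRUE
      keep[k] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Similarity between two product-ion spectra
#'
#' The per-spectrum kernel of the search engine. Peaks are paired
#' one-to-one, greedily by smallest absolute m/z difference within
#' `mzMatchTol`; the score is
#' \deqn{100 \cdot \frac{\sum_{matched} \sqrt{I_q I_r}}
#'   {\sqrt{\sum_q I \cdot \sum_r I}}}
#' a geometric-mean-intensity matched-peak statistic in \[0, 100\]. It is
#' symmetric, invariant under uniform intensity scaling of either spectrum,
#' and reaches 100 exactly when the two spectra are identical up to such a
#' scaling. Both spectra are assumed to have passed the intensity cutoff.
#'
#' @param query,reference [MassSpectrum-class] objects.
#' @param mzMatchTol Absolute fragment m/z tolerance in Th (default 0.01).
#' @return A score in \[0, 100\]. An empty spectrum yields 0 with a
#'   warning.
#' @examples
#' a <- MassSpectrum(c(100, 150), c(100, 50))
#' spectrumSimilarity(a, a)
#' @export
spectrumSimilarity <- function(query, reference, mzMatchTol = 0.01) {
  stopifnot(is(query, "MassSpectrum"), is(reference, "MassSpectrum"))
  if (!peaksCount(query) || !peaksCount(reference)) {
    warning("empty spectrum in similarity computation; score is 0")
    return(0)
  }
  m <- matchPeaks(mz(query), mz(reference), mzMatchTol)
  if (!nrow(m)) return(0)
  num <- sum(sqrt(intensity(query)[m[, 1]] * intensity(reference)[m[, 2]]))
  100 * num / sqrt(sum(intensity(query)) * sum(intensity(reference)))
}

#' Score one candidate compound against a query spectrum
#'
#' Computes the two compound-level match-probability values for one
#' candidate entry within its candidate context:
#' * `amp` (average match probability): the arithmetic mean of
#'   [spectrumSimilarity()] over **all** reference spectra of the entry's
#'   multi-collision-energy set;
#' * `ramp` (relative average match probability):
#'   `100 * amp(entry) / sum(amp over the candidate context)`, i.e. how
#'   strongly the entry dominates the other precursor-matched candidates
#'   (100 for a sole positive candidate; 0 when every candidate amp is 0).
#'
#' @param query An MS2 [MassSpectrum-class] (intensity cutoff already
#'   applied by the caller, as in [identifySpectrum()]).
#' @param entry The [LibraryEntry-class] to score.
#' @param candidatesContext The full [candidateFilter()] output for this
#'   query; must contain `entry`.
#' @param params A [SearchParams-class].
#' @return A one-row data frame (columns `compound_id`, `name`, `amp`,
#'   `ramp`, `precursor_error`, `n_reference_spectra_used`,
#'   `best_reference_ce`).
#' @export
scoreCompound <- function(query, entry, candidatesContext,
                          params = SearchParams()) {
  ids <- vapply(candidatesContext, compoundId, character(1))
  if (!compoundId(entry) %in% ids)
    stop("contract violation: entry ", compoundId(entry),
         " is not part of the candidate context")
  amps <- vapply(candidatesContext, function(e)
    entryAmp(query, e, params@mzMatchTol), numeric(1))
  names(amps) <- ids
  total <- sum(amps)
  amp <- amps[[compoundId(entry)]]
  ramp <- if (total > 0) 100 * amp / total else 0
  sims <- vapply(referenceSpectra(entry), function(r)
    spectrumSimilarity(query, r, params@mzMatchTol), numeric(1))
  bestCe <- collisionEnergy(referenceSpectra(entry)[[which.max(sims)]])
  data.frame(
    compound_id = compoundId(entry), name = compoundName(entry),
    amp = amp, ramp = ramp,
    precursor_error = precursorMz(query) - precursorMz(entry),
    n_reference_spectra_used = length(entry), best_reference_ce = bestCe,
    stringsAsFactors = FALSE)
}

## Internal: amp of one entry = mean kernel similarity over its reference
## spectra.
entryAmp <- function(query, entry, mzMatchTol) {
  mean(vapply(referenceSpectra(entry), function(r)
    spectrumSimilarity(query, r, mzMatchTol), numeric(1)))
}

#' Identify a query spectrum against a library
#'
#' The full per-spectrum pipeline: intensity cutoff on the query, precursor
#' candidate filtering, amp/ramp scoring of every candidate, and ranking by
#' amp descending (ties: higher ramp, then smaller absolute precursor
#' error, then lexicographic compound id). A tentative positive
#' identification is declared iff the top-ranked candidate satisfies the
#' strict decision rule `amp > ampThreshold` and `ramp > rampThreshold`
#' (defaults 5.0 and 40.0) with the precursor error within tolerance.
#'
#' @param query An MS2 [MassSpectrum-class].
#' @param library A [SpectralLibrary-class].
#' @param params A [SearchParams-class].
#' @return A list with `matches` (ranked data frame as in
#'   [scoreCompound()], zero rows when no candidate passes the precursor
#'   filter) and `identification` (one-row data frame with
#'   `review_status = "auto_tentative"`, or `NULL` when the decision rule
#'   fails).
#' @export
identifySpectrum <- function(query, library, params = SearchParams()) {
  q <- applyIntensityCutoff(query, params@intensityCutoffFactor)
  cands <- candidateFilter(q, library, params@precursorTol)
  if (!length(cands))
    return(list(matches = emptyMatches(), identification = NULL))
  rows <- lapply(cands, scoreCompound, query = q,
                 candidatesContext = cands, params = params)
  matches <- do.call(rbind, rows)
  o <- order(-matches$amp, -matches$ramp, abs(matches$precursor_error),
             matches$compound_id)
  matches <- matches[o, , drop = FALSE]
  rownames(matches) <- NULL
  top <- matches[1, , drop = FALSE]
  identification <- NULL
  if (top$amp > params@ampThreshold && top$ramp > params@rampThreshold &&
      abs(top$precursor_error) <= params@precursorTol) {
    identification <- cbind(top,
      data.frame(scan_id = scanId(query), rt = rtime(query),
                 review_status = "auto_tentative", stringsAsFactors = FALSE))
  }
  list(matches = matches, identification = identification)
}

emptyMatches <- function() {
  data.frame(compound_id = character(), name = character(), amp = numeric(),
             ramp = numeric(), precursor_error = numeric(),
             n_reference_spectra_used = integer(),
             best_reference_ce = numeric(), stringsAsFactors = FALSE)
}

#' Screen a whole run against a library
#'
#' Searches every MS2 spectrum of the run with [identifySpectrum()] and
#' aggregates the spectrum-level tentative hits into one identification per
#' compound, keeping the highest-amp spectrum. The report exposes both the
#' spectrum-level and the compound-level tallies.
#'
#' @param run An [MsRun-class].
#' @param library A [SpectralLibrary-class].
#' @param params A [SearchParams-class].
#' @return An object of class `"screeningReport"`: a list with
#'   `spectra_searched`, `spectrum_hits` (data frame, one row per tentative
#'   spectrum-level hit), `n_tentative_spectrum`, `identifications` (data
#'   frame, one row per compound, `review_status = "auto_tentative"`) and
#'   `n_tentative_compound`.
#' @seealso [reviewHits()]
#' @export
screenRun <- function(run, library, params = SearchParams()) {
  sps <- ms2Spectra(run)
  hits <- list()
  for (sp in sps) {
    res <- identifySpectrum(sp, library, params)
    if (!is.null(res$identification))
      hits[[length(hits) + 1L]] <- res$identification
  }
  spectrumHits <- if (length(hits)) do.call(rbind, hits) else
    cbind(emptyMatches(),
          data.frame(scan_id = character(), rt = numeric(),
                     review_status = character(), stringsAsFactors = FALSE))
  identifications <- spectrumHits[0, , drop = FALSE]
  if (nrow(spectrumHits)) {
    best <- vapply(split(seq_len(nrow(spectrumHits)),
                         spectrumHits$compound_id),
                   function(idx) idx[which.max(spectrumHits$amp[idx])],
                   integer(1))
    identifications <- spectrumHits[sort(best), , drop = FALSE]
    rownames(identifications) <- NULL
  }
  structure(list(
    spectra_searched = length(sps),
    spectrum_hits = spectrumHits,
    n_tentative_spectrum = nrow(spectrumHits),
    identifications = identifications,
    n_tentative_compound = nrow(identifications)),
    class = "screeningReport")
}

#' @export
print.screeningReport <- function(x, ...) {
  cat(sprintf(
    "Screening report | %d MS2 spectra searched | %d tentative hits (%d compounds)\n",
    x$spectra_searched, x$n_tentative_spectrum, x$n_tentative_compound))
  if (!is.null(x$n_confirmed))
    cat(sprintf("  reviewed: %d confirmed, %d rejected, %d unreviewed\n",
                x$n_confirmed, x$n_rejected, x$n_unreviewed))
  invisible(x)
}

#' Review tentative identifications
#'
#' The expert-review stage: each tentative compound identification is
#' confirmed or rejected according to a review oracle (in tests, the
#' simulator's ground truth; in practice, the expert's verdicts). Compounds
#' missing from the oracle stay `"unreviewed"` and are flagged with a
#' warning.
#'
#' @param report A `"screeningReport"` from [screenRun()].
#' @param oracle Named logical vector mapping `compound_id` to `TRUE`
#'   (confirm) or `FALSE` (reject).
#' @return The report with `review_status` updated on `identifications`
#'   and added counts `n_confirmed`, `n_rejected`, `n_unreviewed`.
#' @export
reviewHits <- function(report, oracle) {
  stopifnot(inherits(report, "screeningReport"), is.logical(oracle))
  ids <- report$identifications$compound_id
  status <- rep("unreviewed", length(ids))
  known <- ids %in% names(oracle)
  status[known] <- ifelse(oracle[ids[known]], "confirmed", "rejected")
  if (any(!known))
    warning("review oracle missing ", sum(!known),
            " compound(s); left unreviewed")
  report$identifications$review_status <- status
  report$n_confirmed <- sum(status == "confirmed")
  report$n_rejected <- sum(status == "rejected")
  report$n_unreviewed <- sum(status == "unreviewed")
  report
}
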