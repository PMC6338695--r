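# Shared fixtures and independent oracles for the test suite.

# Small deterministic MS2 spectrum.
msp2 <- function(mz, intensity, precursorMz = 300, ce = 35, rt = 10,
                 scanId = "q") {
  MassSpectrum(mz = mz, intensity = intensity, precursorMz = precursorMz,
               rtime = rt, collisionEnergy = ce, msLevel = 2L,
               scanId = scanId)
}

# A random centroided MS2 spectrum with distinct m/z values.
randomSpectrum <- function(nPeaks = 10, mzRange = c(60, 400),
                           precursorMz = 420, ce = 35, rt = 10,
                           scanId = "rnd") {
  mzs <- sort(runif(nPeaks, mzRange[1], mzRange[2]))
  while (any(diff(mzs) < 0.05))
    mzs <- sort(runif(nPeaks, mzRange[1], mzRange[2]))
  msp2(mzs, runif(nPeaks, 1, 1000), precursorMz, ce, rt, scanId)
}

# Independent exhaustive one-to-one assignment oracle for the similarity
# kernel: enumerates every one-to-one matching of within-tolerance peak
# pairs, keeps the maximal ones, selects the matching whose ascending
# |delta m/z| sequence is lexicographically smallest (the declared
# matching preference), and scores it. Exponential; for spectra with few
# peaks only.
oracleSimilarity <- function(query, reference, tol = 0.01) {
  qmz <- mz(query); rmz <- mz(reference)
  qint <- intensity(query); rint <- intensity(reference)
  if (!length(qmz) || !length(rmz)) return(0)
  d <- abs(outer(qmz, rmz, "-"))
  pairs <- which(d <= tol, arr.ind = TRUE)
  if (!nrow(pairs)) return(0)
  matchings <- list()
  rec <- function(k, usedQ, usedR, chosen) {
    if (k > nrow(pairs)) {
      matchings[[length(matchings) + 1L]] <<- chosen
      return(invisible(NULL))
    }
    rec(k + 1L, usedQ, usedR, chosen)
    qi <- pairs[k, 1]; ri <- pairs[k, 2]
    if (!(qi %in% usedQ) && !(ri %in% usedR))
      rec(k + 1L, c(usedQ, qi), c(usedR, ri), c(chosen, k))
  }
  rec(1L, integer(), integer(), integer())
  isMaximal <- function(chosen) {
    usedQ <- pairs[chosen, 1]; usedR <- pairs[chosen, 2]
    for (k in seq_len(nrow(pairs)))
      if (!(pairs[k, 1] %in% usedQ) && !(pairs[k, 2] %in% usedR))
        return(FALSE)
    TRUE
  }
  maximal <- Filter(isMaximal, matchings)
  deltas <- lapply(maximal, function(ch) sort(d[pairs[ch, , drop = FALSE]]))
  maxLen <- max(lengths(deltas))
  padded <- do.call(rbind, lapply(deltas, function(x)
    c(x, rep(Inf, maxLen - length(x)))))
  best <- maximal[[do.call(order, as.data.frame(padded))[1]]]
  num <- sum(sqrt(qint[pairs[best, 1]] * rint[pairs[best, 2]]))
  100 * num / sqrt(sum(qint) * sum(rint))
}

# Minimal hand-built library: nEntries compounds, one reference spectrum
# each, well-separated precursors.
tinyLibrary <- function(nEntries = 3, precursors = 300 + seq_len(nEntries)) {
  entries <- lapply(seq_len(nEntries), function(i) {
    cmp <- CompoundRecord(sprintf("T%02d", i), sprintf("tiny-%02d", i),
                          precursors[i], logp = 2)
    sp <- msp2(c(100 + i, 150 + i, 200 + i), c(1000, 400, 120),
               precursorMz = precursors[i], ce = 35,
               scanId = sprintf("T%02d_ref", i))
    LibraryEntry(cmp, list(sp))
  })
  SpectralLibrary(entries = entries, version = "tiny")
}
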