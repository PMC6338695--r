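test_that("candidate filtering applies the absolute precursor tolerance", {
  lib <- tinyLibrary(3, precursors = c(310.2166, 310.2300, 350.0))
  q <- msp2(c(100, 150), c(10, 5), precursorMz = 310.2171)
  cands <- candidateFilter(q, lib, 0.01)
  expect_length(cands, 1L)
  expect_equal(compoundId(cands[[1]]), "T01")  # error -0.0005, within 0.01
  # isobaric entries are all returned, in library order
  iso <- tinyLibrary(2, precursors = c(310.2166, 310.2168))
  expect_length(candidateFilter(q, iso, 0.01), 2L)
  # out-of-tolerance query yields an empty candidate set
  far <- msp2(100, 10, precursorMz = 500)
  expect_length(candidateFilter(far, lib, 0.01), 0L)
})

test_that("similarity kernel: self-match 100, disjoint 0, frozen example", {
  a <- msp2(c(100, 150, 200), c(1000, 400, 100))
  expect_equal(spectrumSimilarity(a, a), 100)
  # invariance under uniform intensity scaling
  b <- msp2(c(100, 150, 200), 7.3 * c(1000, 400, 100))
  expect_equal(spectrumSimilarity(a, b), 100)
  disjoint <- msp2(c(120, 170), c(10, 10))
  expect_equal(spectrumSimilarity(a, disjoint), 0)
  # frozen value from the exhaustive assignment oracle:
  # query {(100.00,100),(150.00,50)} vs reference {(100.005,80),(200.00,20)}
  q <- msp2(c(100.00, 150.00), c(100, 50))
  r <- msp2(c(100.005, 200.00), c(80, 20))
  expect_equal(spectrumSimilarity(q, r), oracleSimilarity(q, r))
  expect_equal(spectrumSimilarity(q, r), 73.0297, tolerance = 1e-4)
  # symmetric; empty spectrum scores 0 with a warning
  expect_equal(spectrumSimilarity(r, q), spectrumSimilarity(q, r))
  expect_warning(s0 <- spectrumSimilarity(q, msp2(numeric(), numeric())),
                 "empty")
  expect_equal(s0, 0)
})

test_that("similarity equals the exhaustive assignment oracle on small spectra", {
  withr::local_seed(41)
  for (rep in 1:40) {
    nq <- sample(1:6, 1); nr <- sample(1:6, 1)
    # narrow m/z band to force overlapping tolerance windows
    q <- msp2(sort(runif(nq, 100, 100.06)), runif(nq, 1, 100))
    r <- msp2(sort(runif(nr, 100, 100.06)), runif(nr, 1, 100))
    expect_equal(spectrumSimilarity(q, r), oracleSimilarity(q, r),
                 tolerance = 1e-12)
  }
})

test_that("amp averages the reference set; ramp normalises over candidates", {
  # three isobaric candidates: ramp values proportional to amp, summing 100
  prec <- 400.2
  mk <- function(id, refMz) {
    cmp <- CompoundRecord(id, id, prec, logp = 2)
    LibraryEntry(cmp, list(msp2(refMz, c(1000, 300, 100),
                                precursorMz = prec, ce = 35)))
  }
  lib <- SpectralLibrary(entries = list(
    mk("A", c(100, 150, 200)), mk("B", c(100, 150, 250)),
    mk("C", c(300, 320, 340))))
  q <- msp2(c(100, 150, 200), c(1000, 300, 100), precursorMz = prec)
  cands <- candidateFilter(q, lib, 0.01)
  rows <- lapply(cands, scoreCompound, query = q, candidatesContext = cands,
                 params = SearchParams())
  m <- do.call(rbind, rows)
  expect_equal(m$amp[1], 100)
  expect_equal(sum(m$ramp), 100)
  expect_equal(m$ramp, 100 * m$amp / sum(m$amp))
  expect_equal(m$amp[3], 0)  # disjoint candidate
  # two candidates with equal amp split ramp 50/50
  lib2 <- SpectralLibrary(entries = list(mk("A", c(100, 150, 200)),
                                         mk("B", c(100, 150, 200))))
  cands2 <- candidateFilter(q, lib2, 0.01)
  m2 <- do.call(rbind, lapply(cands2, scoreCompound, query = q,
                              candidatesContext = cands2))
  expect_equal(m2$ramp, c(50, 50))
  # sole candidate with positive amp has ramp 100
  sole <- SpectralLibrary(entries = list(mk("A", c(100, 150, 200))))
  cands3 <- candidateFilter(q, sole, 0.01)
  expect_equal(scoreCompound(q, cands3[[1]], cands3)$ramp, 100)
  # entry outside its declared context is a contract violation
  expect_error(scoreCompound(q, mk("Z", c(500, 520, 540)), cands3),
               "contract violation")
})

test_that("adding an unrelated candidate never changes others; a competing one dilutes ramp", {
  prec <- 400.2
  mk <- function(id, refMz, ints = c(1000, 300, 100)) {
    cmp <- CompoundRecord(id, id, prec, logp = 2)
    LibraryEntry(cmp, list(msp2(refMz, ints, precursorMz = prec, ce = 35)))
  }
  q <- msp2(c(100, 150, 200), c(1000, 300, 100), precursorMz = prec)
  base <- list(mk("A", c(100, 150, 200)), mk("B", c(100, 250, 280)))
  mBase <- do.call(rbind, lapply(base, scoreCompound, query = q,
                                 candidatesContext = base))
  # amp-0 candidate: no effect on amp or ramp of the others
  withZero <- c(base, list(mk("Z", c(500, 520, 540))))
  mZero <- do.call(rbind, lapply(withZero, scoreCompound, query = q,
                                 candidatesContext = withZero))
  expect_equal(mZero$amp[1:2], mBase$amp)
  expect_equal(mZero$ramp[1:2], mBase$ramp)
  # competing amp > 0 candidate strictly decreases every other ramp
  withComp <- c(base, list(mk("D", c(100, 150, 320))))
  mComp <- do.call(rbind, lapply(withComp, scoreCompound, query = q,
                                 candidatesContext = withComp))
  expect_true(all(mComp$ramp[1:2] < mBase$ramp))
  expect_equal(mComp$amp[1:2], mBase$amp)
})

test_that("identifySpectrum ranks by amp and applies the strict decision rule", {
  gl <- generateLibrary(50, seed = 3)
  q <- generateQuerySpectra(gl$profiles[["CMP0007"]], n = 1, seed = 99)[[1]]
  res <- identifySpectrum(q, gl$library)
  expect_equal(res$matches$compound_id[1], "CMP0007")
  expect_s3_class(res$identification, "data.frame")
  expect_equal(res$identification$review_status, "auto_tentative")
  expect_true(res$identification$amp > 5 && res$identification$ramp > 40)
  # boundary is strict: amp exactly at the threshold fails
  p <- SearchParams(ampThreshold = res$matches$amp[1])
  expect_null(identifySpectrum(q, gl$library, p)$identification)
  # no candidates -> empty result
  none <- msp2(c(100, 150), c(10, 5), precursorMz = 99.5)
  out <- identifySpectrum(none, gl$library)
  expect_equal(nrow(out$matches), 0L)
  expect_null(out$identification)
})

test_that("query intensity scaling leaves amp unchanged", {
  gl <- generateLibrary(5, seed = 13)
  q <- generateQuerySpectra(gl$profiles[[2]], n = 1, seed = 8)[[1]]
  scaled <- initialize(q, intensity = intensity(q) * 1234.5)
  expect_equal(identifySpectrum(q, gl$library)$matches$amp,
               identifySpectrum(scaled, gl$library)$matches$amp)
})

test_that("screenRun aggregates spectrum hits into per-compound identifications", {
  gl <- generateLibrary(8, seed = 17)
  p <- gl$profiles[[4]]
  qs <- generateQuerySpectra(p, n = 3, seed = 4)
  run <- MsRun(spectra = qs)
  rep <- screenRun(run, gl$library)
  expect_equal(rep$spectra_searched, 3L)
  expect_equal(rep$n_tentative_spectrum, 3L)
  expect_equal(rep$n_tentative_compound, 1L)
  expect_equal(rep$identifications$compound_id, compoundId(p))
  expect_equal(rep$identifications$amp, max(rep$spectrum_hits$amp))
  # empty run
  rep0 <- screenRun(MsRun(), gl$library)
  expect_equal(rep0$spectra_searched, 0L)
  expect_equal(rep0$n_tentative_compound, 0L)
})

test_that("review confirms or rejects tentative identifications", {
  # scaled tally matching the review bookkeeping: 230 tentative, 83 rejected
  ids <- data.frame(compound_id = sprintf("C%03d", 1:230),
                    review_status = "auto_tentative",
                    stringsAsFactors = FALSE)
  report <- structure(list(spectra_searched = 11437, spectrum_hits = ids,
                           n_tentative_spectrum = 230,
                           identifications = ids,
                           n_tentative_compound = 230),
                      class = "screeningReport")
  oracle <- setNames(rep(TRUE, 230), ids$compound_id)
  oracle[1:83] <- FALSE
  reviewed <- reviewHits(report, oracle)
  expect_equal(reviewed$n_confirmed, 147)
  expect_equal(reviewed$n_rejected, 83)
  expect_equal(reviewed$n_unreviewed, 0)
  # all-true oracle: zero rejections
  allTrue <- reviewHits(report, setNames(rep(TRUE, 230), ids$compound_id))
  expect_equal(allTrue$n_rejected, 0)
  # missing compounds stay unreviewed, with a warning
  expect_warning(part <- reviewHits(report, oracle[1:10]), "missing")
  expect_equal(part$n_unreviewed, 220)
  # empty report passes through
  empty <- screenRun(MsRun(), tinyLibrary(1))
  expect_equal(reviewHits(empty, oracle)$n_confirmed, 0)
})
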