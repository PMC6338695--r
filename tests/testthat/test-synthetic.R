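test_that("breakdown spectra follow the template grid and are deterministic", {
  gl <- generateLibrary(2, seed = 2)
  p <- gl$profiles[[1]]
  sps <- generateBreakdownSpectra(p)
  expect_length(sps, 10L)  # default 5-50 eV grid in ten steps
  expect_equal(vapply(sps, collisionEnergy, numeric(1)), seq(5, 50, 5))
  # below every appearance CE only the surviving precursor remains
  cmp <- CompoundRecord("X", "x", 300.15)
  prof <- AnalyteProfile(cmp, data.frame(mz = 120.05, appearanceCe = 20,
                                         ceOpt = 30, maxRel = 80),
                         rtApex = 100, rtWidth = 8, responseFactor = 50)
  low <- generateBreakdownSpectra(prof, ceGrid = 10)[[1]]
  expect_equal(mz(low), 300.15)
  # regeneration with the same seed is bit-identical
  a <- generateBreakdownSpectra(p, seed = 7, noiseSigma = 0.1)
  b <- generateBreakdownSpectra(p, seed = 7, noiseSigma = 0.1)
  expect_identical(lapply(a, mz), lapply(b, mz))
  expect_identical(lapply(a, intensity), lapply(b, intensity))
})

test_that("generated libraries meet spacing, isobar and scale contracts", {
  gl <- generateLibrary(50, seed = 1, isobarFraction = 0)
  expect_equal(length(gl$library), 50L)
  prec <- vapply(entries(gl$library), precursorMz, numeric(1))
  expect_true(min(dist(prec)) > 0.01)  # no accidental isobars
  for (e in entries(gl$library))
    expect_true(isTRUE(validObject(e, test = TRUE)))
  # isobarFraction 1 with n = 2 yields one isobaric pair
  iso <- generateLibrary(2, seed = 4, isobarFraction = 1)
  prec2 <- vapply(entries(iso$library), precursorMz, numeric(1))
  expect_lte(abs(diff(prec2)), 0.01)
  # determinism
  expect_identical(
    vapply(entries(generateLibrary(10, seed = 9)$library), precursorMz,
           numeric(1)),
    vapply(entries(generateLibrary(10, seed = 9)$library), precursorMz,
           numeric(1)))
})

test_that("matrix background stays clear of precursors and keeps positive TIC", {
  expect_equal(nrow(generateMatrixBackground(nPeaks = 0, seed = 1)$ions), 0L)
  avoid <- c(250.1234, 300.5678)
  bg <- generateMatrixBackground(nPeaks = 30, seed = 3, avoidMzs = avoid)
  expect_true(all(vapply(bg$ions$mz, function(m)
    min(abs(m - avoid)) > 0.011, logical(1))))
  # a matrix-loaded blank has TIC strictly above a reagent blank at all times
  tic <- backgroundTic(bg, seq(0, 600, by = 10))
  expect_true(all(tic > 0))
  # seeded regeneration is identical
  expect_identical(generateMatrixBackground(nPeaks = 10, seed = 5)$ions,
                   generateMatrixBackground(nPeaks = 10, seed = 5)$ions)
})

test_that("DDA exclusion: 30 s ban after two occurrences of a precursor", {
  cmp <- CompoundRecord("E1", "eluter", 400.2)
  # broad peak so the precursor stays above threshold the whole run
  prof <- AnalyteProfile(cmp, data.frame(mz = c(120.05, 180.1),
                                         appearanceCe = c(8, 10),
                                         ceOpt = c(18, 20),
                                         maxRel = c(90, 60)),
                         rtApex = 50, rtWidth = 500, responseFactor = 100)
  sim <- simulateDdaRun(list(prof), 50, duration = 100, seed = 1)
  ev <- sim$events[sim$events$source == "E1", ]
  expect_gte(nrow(ev), 3L)
  # selected in the first cycle, twice in a row, then banned for 30 s
  expect_equal(ev$time[1], 0)
  expect_lt(ev$time[2] - ev$time[1], 30)
  expect_gt(ev$time[3] - ev$time[2], 30)
  # invariant: never more than exclusionAfter selections in any 30 s window
  for (k in seq_len(nrow(ev)))
    expect_lte(sum(ev$time >= ev$time[k] & ev$time < ev$time[k] + 30), 2L)
})

test_that("DDA trigger threshold: a 99-count analyte yields no MS2", {
  cmp <- CompoundRecord("W1", "weak", 350.1)
  prof <- AnalyteProfile(cmp, data.frame(mz = 120.05, appearanceCe = 8,
                                         ceOpt = 18, maxRel = 90),
                         rtApex = 10, rtWidth = 500, responseFactor = 99)
  sim <- simulateDdaRun(list(prof), 1, duration = 20, seed = 1)
  expect_equal(nrow(sim$events), 0L)
  expect_length(sim$detected, 0L)
  # a concentration of 0 removes the analyte entirely
  sim0 <- simulateDdaRun(list(prof), 0, duration = 20, seed = 1)
  expect_true(all(vapply(spectra(sim0$run), peaksCount, integer(1)) == 0L))
})

test_that("DDA top-N: the ninth co-eluting analyte is not selected in the cycle", {
  profs <- lapply(1:9, function(i) {
    cmp <- CompoundRecord(sprintf("N%d", i), sprintf("n%d", i), 300 + i)
    AnalyteProfile(cmp, data.frame(mz = 120.05, appearanceCe = 8,
                                   ceOpt = 18, maxRel = 90),
                   rtApex = 0, rtWidth = 1000,
                   responseFactor = 100 * (10 - i))  # descending intensity
  })
  dda <- DdaParams()
  sim <- simulateDdaRun(profs, rep(10, 9), dda = dda,
                        duration = ddaCycleTime(dda), seed = 1)
  firstCycle <- sim$events[sim$events$time == 0, ]
  expect_equal(nrow(firstCycle), 8L)
  expect_false("N9" %in% firstCycle$source)
  expect_setequal(firstCycle$source, sprintf("N%d", 1:8))
})

test_that("simulated runs respect the survey and MS/MS scan ranges", {
  gl <- generateLibrary(5, seed = 6)
  profs <- gl$profiles
  for (i in seq_along(profs)) profs[[i]]@rtApex <- 20 + (i - 1) * 25
  bg <- generateMatrixBackground(nPeaks = 15, seed = 6,
                                 avoidMzs = vapply(profs, precursorMz,
                                                   numeric(1)))
  sim <- simulateDdaRun(profs, rep(30, 5), background = bg,
                        duration = 130, seed = 6)
  for (sp in spectra(sim$run)) {
    if (!peaksCount(sp)) next
    rng <- if (msLevel(sp) == 1L) c(100, 700) else c(50, 700)
    expect_true(all(mz(sp) >= rng[1] & mz(sp) <= rng[2]))
  }
  # determinism of the full simulator
  sim2 <- simulateDdaRun(profs, rep(30, 5), background = bg,
                         duration = 130, seed = 6)
  expect_identical(sim$events, sim2$events)
  expect_identical(lapply(spectra(sim$run), mz),
                   lapply(spectra(sim2$run), mz))
})

test_that("mzML-lite round trip of a simulated run matches the in-memory object", {
  gl <- generateLibrary(3, seed = 8)
  profs <- gl$profiles
  for (i in seq_along(profs)) profs[[i]]@rtApex <- 15 + (i - 1) * 20
  sim <- simulateDdaRun(profs, rep(20, 3), duration = 60, seed = 8)
  path <- withr::local_tempfile(fileext = ".xml")
  writeMzmlLite(sim$run, path)
  back <- readMzmlLite(path)
  expect_equal(length(back), length(sim$run))
  expect_equal(vapply(spectra(back), msLevel, integer(1)),
               vapply(spectra(sim$run), msLevel, integer(1)))
  for (i in seq_along(spectra(back))) {
    expect_equal(mz(spectra(back)[[i]]), mz(spectra(sim$run)[[i]]),
                 tolerance = 1e-6)
    expect_equal(intensity(spectra(back)[[i]]),
                 intensity(spectra(sim$run)[[i]]),
                 tolerance = 1e-5)
  }
})

test_that("dilution experiment: seven runs, manifest thresholds, volume invariance", {
  gl <- generateLibrary(6, seed = 10)
  d400 <- generateDilutionExperiment(gl$profiles, extractionVolume = 400,
                                     seed = 12)
  expect_length(d400$runs, 7L)
  expect_equal(unique(d400$manifest$dilution_factor), 1.8)
  # expected detectability is monotone in concentration per compound
  for (id in unique(d400$manifest$compound_id)) {
    sub <- d400$manifest[d400$manifest$compound_id == id, ]
    sub <- sub[order(sub$level), ]
    expect_true(all(diff(as.integer(sub$expected_detectable)) >= 0))
  }
  # 4 mL extraction volume: same seed, same neat amounts -> identical
  # detection ground truth despite a 9x dilution factor
  d4000 <- generateDilutionExperiment(gl$profiles, extractionVolume = 4000,
                                      seed = 12)
  expect_equal(unique(d4000$manifest$dilution_factor), 9)
  expect_identical(d400$manifest$expected_detectable,
                   d4000$manifest$expected_detectable)
  for (lev in names(d400$runs))
    expect_identical(d400$runs[[lev]]$detected, d4000$runs[[lev]]$detected)
})
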