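test_that("specificity arithmetic and its ordering guard", {
  r <- computeSelectivity(11437, 230, 83)
  expect_equal(r$specificity, 99.3)
  expect_equal(r$specificity_exact + 100 * 83 / 11437, 100)
  expect_equal(computeSelectivity(100, 0, 0)$specificity, 100.0)
  expect_equal(computeSelectivity(1000, 50, 16)$specificity, 98.4)
  expect_error(computeSelectivity(100, 10, 20), "ordering")
})

test_that("false-negative rate arithmetic", {
  expect_equal(computeFnRate(500, 0), 0)
  expect_equal(computeFnRate(10, 10), 100)
  expect_equal(computeFnRate(200, 3), 1.5)
  expect_warning(nan <- computeFnRate(0, 0), "undefined")
  expect_true(is.nan(nan))
})

test_that("LOI is the minimum identified level, with inconsistency flag", {
  levels <- c(1, 2.5, 5, 10, 25, 50, 100)
  r <- determineLoi(levels, levels %in% c(5, 10, 25, 50, 100))
  expect_equal(r$loi, 5)
  expect_false(r$inconsistent)
  none <- determineLoi(levels, rep(FALSE, 7))
  expect_false(none$detected)
  expect_true(is.na(none$loi))
  # identified at 2.5 but missed at 5: same minimum, flagged
  holes <- determineLoi(levels, levels %in% c(2.5, 10, 25, 50, 100))
  expect_equal(holes$loi, 2.5)
  expect_true(holes$inconsistent)
  # order of the input levels must not matter
  shuffled <- determineLoi(rev(levels), rev(levels) %in% c(5, 10, 25, 50, 100))
  expect_equal(shuffled$loi, 5)
})

test_that("LOI is monotone in the identified set", {
  withr::local_seed(51)
  levels <- c(1, 2.5, 5, 10, 25, 50, 100)
  for (rep in 1:25) {
    ident <- runif(7) < 0.5
    if (!any(ident)) next
    base <- determineLoi(levels, ident)$loi
    # adding one identified lower level never raises the LOI
    off <- which(!ident & levels < base)
    if (length(off)) {
      ident2 <- ident
      ident2[sample(off, 1)] <- TRUE
      expect_lte(determineLoi(levels, ident2)$loi, base)
    }
  }
})

test_that("logP window classes with inclusive boundaries", {
  expect_equal(logpWindowClass(-1.1), "too_polar")   # gabapentin-like
  expect_equal(logpWindowClass(3.0), "in_window")
  expect_equal(logpWindowClass(0.5), "in_window")
  expect_equal(logpWindowClass(5.5), "in_window")
  expect_equal(logpWindowClass(5.51), "too_apolar")
  expect_equal(logpWindowClass(NA), "unknown")
  expect_equal(logpWindowClass(c(-1, 2, 7)),
               c("too_polar", "in_window", "too_apolar"))
})

test_that("two-method agreement arithmetic", {
  withr::local_seed(61)
  # identical sets agree 100%
  a <- data.frame(sample = "s1", compound = c("x", "y"))
  eq <- compareMethods(a, a)
  expect_equal(eq$pct_both, 100)
  expect_equal(eq$only_a + eq$only_b, 0)
  # random small sets equal brute-force set arithmetic
  for (rep in 1:10) {
    sa <- paste0("s", sample(1:5, 20, TRUE), ":", sample(letters[1:6], 20, TRUE))
    sb <- paste0("s", sample(1:5, 20, TRUE), ":", sample(letters[1:6], 20, TRUE))
    cmp <- compareMethods(sa, sb)
    expect_equal(cmp$both, length(intersect(unique(sa), unique(sb))))
    expect_equal(cmp$only_a, length(setdiff(unique(sa), unique(sb))))
    expect_equal(cmp$only_b, length(setdiff(unique(sb), unique(sa))))
    expect_equal(cmp$total, cmp$both + cmp$only_a + cmp$only_b)
    # percentages sum to 100 up to one-decimal rounding
    expect_equal(cmp$pct_both + cmp$pct_only_a + cmp$pct_only_b, 100,
                 tolerance = 0.15)
  }
})

test_that("miss explanation partitions by fixed priority order", {
  lib <- tinyLibrary(3)  # covers T01..T03
  logpTable <- data.frame(
    compound = c("T01", "T02", "T03", "uncovered"),
    logp = c(6.2, 2.0, 3.0, 1.0))
  concTable <- data.frame(
    sample = c("s1", "s1", "s2", "s3"),
    compound = c("T01", "T02", "T03", "uncovered"),
    concentration = c(50, 1.2, 80, 2))
  misses <- data.frame(
    sample = c("s1", "s1", "s2", "s3"),
    compound = c("T01", "T02", "T03", "uncovered"))
  out <- explainMisses(misses, lib, logpTable, concTable)
  expect_equal(unname(c(out$counts)), c(1L, 1L, 1L, 1L))
  # priority: missing spectrum wins over logP and concentration
  expect_equal(out$detail$category[out$detail$compound == "uncovered"],
               "no_reference_spectrum")
  expect_equal(out$detail$category[out$detail$compound == "T01"],
               "outside_logp_window")
  expect_equal(out$detail$category[out$detail$compound == "T02"],
               "below_cutoff")
  expect_equal(out$detail$category[out$detail$compound == "T03"], "other")
  # constructed 10-miss partition equals construction
  misses10 <- data.frame(sample = sprintf("p%d", 1:10),
                         compound = c(rep("nolib", 3), rep("T01", 3),
                                      rep("T02", 2), rep("T03", 2)))
  conc10 <- data.frame(sample = misses10$sample,
                       compound = misses10$compound,
                       concentration = c(rep(50, 3), rep(50, 3),
                                         rep(2, 2), rep(50, 2)))
  out10 <- explainMisses(misses10, lib, logpTable, conc10)
  expect_equal(unname(c(out10$counts)), c(3L, 3L, 2L, 2L))
  expect_equal(unname(c(out10$percentages)), c(30, 30, 20, 20))
  # empty miss set
  out0 <- explainMisses(misses[0, ], lib, logpTable, concTable)
  expect_equal(sum(out0$counts), 0L)
})

test_that("neat-oral-fluid concentration arithmetic", {
  expect_equal(neatConcentration(10, 500, 400), 18)
  expect_equal(neatConcentration(1, 500, 4000), 9)
  expect_equal(neatConcentration(7.7, 500, 0), 7.7)
  expect_error(neatConcentration(1, 0, 400), "volumes")
  expect_error(neatConcentration(1, -5, 400), "volumes")
})
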