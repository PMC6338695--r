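## Performance-evaluation layer: selectivity/specificity, sensitivity,
## limits of identification, logP applicability window, dilution-factor
## arithmetic, and two-method agreement.

#' Selectivity / specificity of the library search
#'
#' From the tallies of a blank-sample experiment — product-ion spectra
#' searched, tentative positive identifications, and false positives sorted
#' out by expert review — computes the specificity of automated library
#' search as `100 * (n_spectra - n_false_positive) / n_spectra`.
#'
#' @param nSpectra Product-ion spectra searched.
#' @param nTentative Tentative positive identifications.
#' @param nFalsePositive False positives rejected by review.
#' @return A list of class `"selectivityResult"` with the three counts,
#'   `specificity` (percent, one decimal, the reporting convention) and
#'   `specificity_exact`.
#' @examples
#' computeSelectivity(11437, 230, 83)$specificity
#' @export
computeSelectivity <- function(nSpectra, nTentative, nFalsePositive) {
  if (!(nFalsePositive <= nTentative && nTentative <= nSpectra) ||
      nFalsePositive < 0)
    stop("count ordering violated: need 0 <= nFalsePositive <= nTentative",
         " <= nSpectra")
  exact <- 100 * (nSpectra - nFalsePositive) / nSpectra
  structure(list(n_spectra = nSpectra, n_tentative = nTentative,
                 n_false_positive = nFalsePositive,
                 specificity = round(exact, 1), specificity_exact = exact),
            class = "selectivityResult")
}

#' @export
print.selectivityResult <- function(x, ...) {
  cat(sprintf(
    "Selectivity | %d spectra, %d tentative, %d false positive | specificity %.1f%%\n",
    x$n_spectra, x$n_tentative, x$n_false_positive, x$specificity))
  invisible(x)
}

#' False-negative rate of the library search
#'
#' Percentage of identifiable spectra (spectra whose true compound is
#' covered by the library) that the automated search missed.
#'
#' @param nIdentifiable Spectra with a library-covered true compound.
#' @param nMissed Of those, the number not identified.
#' @return Percent (`100 * nMissed / nIdentifiable`); `NaN` with a warning
#'   for 0/0.
#' @export
computeFnRate <- function(nIdentifiable, nMissed) {
  stopifnot(nMissed <= nIdentifiable, nMissed >= 0)
  if (nIdentifiable == 0) {
    warning("false-negative rate undefined for 0 identifiable spectra")
    return(NaN)
  }
  100 * nMissed / nIdentifiable
}

#' Limit of identification from a dilution series
#'
#' The LOI is the minimum spiked concentration at which automated library
#' search identified the compound. A non-monotone series (identified at a
#' low level but missed at a higher one) yields the same minimum, flagged
#' inconsistent.
#'
#' @param concentrations Numeric vector of spiked concentrations (ng/mL);
#'   the standard series is `c(1, 2.5, 5, 10, 25, 50, 100)`.
#' @param identified Logical vector, one flag per level.
#' @return A list with `loi` (ng/mL, `NA` when nothing was identified),
#'   `detected` (logical), and `inconsistent` (logical flag).
#' @examples
#' determineLoi(c(1, 2.5, 5, 10, 25, 50, 100),
#'              c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
#' @export
determineLoi <- function(concentrations, identified) {
  stopifnot(length(concentrations) == length(identified),
            length(concentrations) >= 1L, all(concentrations > 0))
  o <- order(concentrations)
  concentrations <- concentrations[o]
  identified <- as.logical(identified)[o]
  if (!any(identified))
    return(list(loi = NA_real_, detected = FALSE, inconsistent = FALSE))
  loi <- min(concentrations[identified])
  inconsistent <- any(!identified & concentrations > loi)
  list(loi = loi, detected = TRUE, inconsistent = inconsistent)
}

#' Classify a compound by the logP applicability window
#'
#' The reversed-phase workflow detects compounds efficiently in the logP
#' window 0.5 to 5.5 (boundaries inclusive); very polar (`logP < 0.5`) and
#' very apolar (`logP > 5.5`) compounds fall outside it.
#'
#' @param logp Numeric vector of octanol-water partition coefficients; `NA`
#'   values are classified `"unknown"`.
#' @param lower,upper Window boundaries (default 0.5 and 5.5).
#' @return Character vector over `{"too_polar", "in_window", "too_apolar",
#'   "unknown"}`.
#' @examples
#' logpWindowClass(c(-1.1, 3, 5.5, NA))
#' @export
logpWindowClass <- function(logp, lower = 0.5, upper = 5.5) {
  out <- ifelse(is.na(logp), "unknown",
         ifelse(logp < lower, "too_polar",
         ifelse(logp > upper, "too_apolar", "in_window")))
  as.character(out)
}

#' Agreement between two identification methods
#'
#' Venn arithmetic over two sets of (sample, compound) identifications,
#' e.g. the non-targeted workflow vs a targeted reference assay.
#' Percentages are relative to the union and reported to one decimal.
#'
#' @param idsA,idsB Data frames with columns `sample` and `compound` (or
#'   character vectors of ready-made keys).
#' @return A list of class `"methodComparison"` with counts `both`,
#'   `only_a`, `only_b`, `total` and the matching percentages `pct_both`,
#'   `pct_only_a`, `pct_only_b`.
#' @examples
#' a <- data.frame(sample = "s1", compound = c("cocaine", "morphine"))
#' b <- data.frame(sample = "s1", compound = c("cocaine", "codeine"))
#' compareMethods(a, b)
#' @export
compareMethods <- function(idsA, idsB) {
  keyify <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("sample", "compound") %in% names(x)))
      unique(paste(x$sample, x$compound, sep = "\r"))
    } else unique(as.character(x))
  }
  a <- keyify(idsA)
  b <- keyify(idsB)
  both <- length(intersect(a, b))
  onlyA <- length(setdiff(a, b))
  onlyB <- length(setdiff(b, a))
  total <- both + onlyA + onlyB
  pct <- function(k) if (total) round(100 * k / total, 1) else NA_real_
  structure(list(both = both, only_a = onlyA, only_b = onlyB, total = total,
                 pct_both = pct(both), pct_only_a = pct(onlyA),
                 pct_only_b = pct(onlyB)),
            class = "methodComparison")
}

#' @export
print.methodComparison <- function(x, ...) {
  cat(sprintf(
    "Method agreement | both %d (%.1f%%) | A only %d (%.1f%%) | B only %d (%.1f%%) | total %d\n",
    x$both, x$pct_both, x$only_a, x$pct_only_a, x$only_b, x$pct_only_b,
    x$total))
  invisible(x)
}

#' Explain identifications missed by the non-targeted workflow
#'
#' Partitions the reference-method-only identifications into explanation
#' categories, each miss being assigned to the FIRST matching category in
#' priority order: missing reference spectrum in the library, logP outside
#' the applicability window, neat concentration below 5 ng/mL, otherwise
#' `"other"`. Compounds absent from every auxiliary table are `"other"`
#' and flagged with a warning.
#'
#' @param misses Data frame with columns `sample` and `compound` (the
#'   reference-only identifications).
#' @param library A [SpectralLibrary-class]; coverage is judged by compound
#'   id.
#' @param logpTable Data frame `compound`, `logp`.
#' @param concentrationTable Data frame `sample`, `compound`,
#'   `concentration` (ng/mL in neat oral fluid).
#' @param concentrationCutoff Concentration (ng/mL) below which a miss is
#'   attributed to the detection capability; default 5.
#' @return A list with `detail` (the input plus a `category` column),
#'   `counts` and `percentages` (one decimal) over the categories
#'   `no_reference_spectrum`, `outside_logp_window`, `below_cutoff`,
#'   `other`.
#' @export
explainMisses <- function(misses, library, logpTable, concentrationTable,
                          concentrationCutoff = 5) {
  stopifnot(all(c("sample", "compound") %in% names(misses)))
  covered <- compoundIds(library)
  logps <- stats::setNames(logpTable$logp, logpTable$compound)
  concKey <- paste(concentrationTable$sample, concentrationTable$compound,
                   sep = "\r")
  concs <- stats::setNames(concentrationTable$concentration, concKey)
  categories <- character(nrow(misses))
  orphan <- 0L
  for (k in seq_len(nrow(misses))) {
    cmp <- misses$compound[k]
    key <- paste(misses$sample[k], cmp, sep = "\r")
    logp <- if (cmp %in% names(logps)) logps[[cmp]] else NA_real_
    conc <- if (key %in% names(concs)) concs[[key]] else NA_real_
    categories[k] <-
      if (!cmp %in% covered) "no_reference_spectrum"
      else if (!is.na(logp) &&
               logpWindowClass(logp) != "in_window") "outside_logp_window"
      else if (!is.na(conc) && conc < concentrationCutoff) "below_cutoff"
      else "other"
    if (categories[k] == "other" && is.na(logp) && is.na(conc))
      orphan <- orphan + 1L
  }
  if (orphan)
    warning(orphan, " miss(es) absent from all auxiliary tables; ",
            "categorised 'other'")
  levelsOrd <- c("no_reference_spectrum", "outside_logp_window",
                 "below_cutoff", "other")
  counts <- table(factor(categories, levels = levelsOrd))
  n <- nrow(misses)
  list(detail = cbind(misses, category = categories),
       counts = counts,
       percentages = if (n) round(100 * counts / n, 1) else counts * NA_real_)
}

#' Concentration in neat oral fluid
#'
#' Converts a concentration measured in the oral fluid / extraction
#' solution mixture back to the neat (undiluted) oral fluid scale:
#' `measured * (vOralFluid + vExtraction) / vOralFluid`. The collection
#' device mixes the specimen with its extraction solution, so all reported
#' drug concentrations refer to the neat fluid.
#'
#' @param measured Concentration measured in the mixture (ng/mL).
#' @param vOralFluid Oral fluid volume (µL), > 0.
#' @param vExtraction Extraction solution volume (µL), >= 0.
#' @return Concentration in neat oral fluid (ng/mL).
#' @examples
#' neatConcentration(10, 500, 400)  # 18 ng/mL
#' @export
neatConcentration <- function(measured, vOralFluid, vExtraction) {
  if (any(vOralFluid <= 0) || any(vExtraction < 0))
    stop("volumes must be positive (extraction volume may be 0)")
  measured * (vOralFluid + vExtraction) / vOralFluid
}
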