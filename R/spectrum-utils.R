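## Internal: evaluate expr with a locally seeded RNG, restoring global state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

#' Discard low-abundance peaks relative to the base peak
#'
#' Retains exactly the peaks whose intensity is at least
#' `cutoffFactor * max(intensity)`; ties at the boundary are kept (`>=`), so
#' the base peak always survives. An empty spectrum passes through
#' unchanged. The operation is idempotent and monotone in the factor.
#'
#' @param spectrum A [MassSpectrum-class].
#' @param cutoffFactor Fraction of the base-peak intensity in \[0, 1);
#'   default 0.01, the screening setting.
#' @return The filtered [MassSpectrum-class].
#' @examples
#' sp <- MassSpectrum(c(100, 150, 200), c(1000, 50, 9))
#' peaksCount(applyIntensityCutoff(sp, 0.01))  # the 9-count peak is lost
#' @export
applyIntensityCutoff <- function(spectrum, cutoffFactor = 0.01) {
  stopifnot(is(spectrum, "MassSpectrum"))
  if (!is.numeric(cutoffFactor) || length(cutoffFactor) != 1L ||
      is.na(cutoffFactor) || cutoffFactor < 0 || cutoffFactor >= 1)
    stop("cutoffFactor must be a single value in [0, 1)")
  if (!peaksCount(spectrum) || cutoffFactor == 0)
    return(spectrum)
  keep <- spectrum@intensity >= cutoffFactor * max(spectrum@intensity)
  initialize(spectrum, mz = spectrum@mz[keep],
             intensity = spectrum@intensity[keep])
}

#' Peak list of a spectrum as a data frame
#'
#' @param spectrum A [MassSpectrum-class].
#' @return A data frame with columns `mz` and `intensity`.
#' @export
peakTable <- function(spectrum) {
  stopifnot(is(spectrum, "MassSpectrum"))
  data.frame(mz = spectrum@mz, intensity = spectrum@intensity)
}
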