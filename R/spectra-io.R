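## Spectrum I/O: MGF, the centroided mzML-lite dialect, and plain-text
## peak-list export.

#' Read a Mascot generic format (MGF) file
#'
#' Parses centroided product-ion spectra from an MGF file: one
#' [MassSpectrum-class] per `BEGIN IONS`/`END IONS` block, `PEPMASS` mapped
#' to the precursor m/z, `RTINSECONDS` to the retention time and
#' `COLLISION_ENERGY` to the collision energy. Blocks without a collision
#' energy receive `defaultCollisionEnergy` (35 eV, the acquisition value).
#' Peaks are sorted by ascending m/z on reading; duplicate m/z centroids
#' are merged by intensity summation. An empty file yields an empty run.
#'
#' @param path Path to an MGF file.
#' @param defaultCollisionEnergy Collision energy (eV) assigned to blocks
#'   lacking one.
#' @return An [MsRun-class].
#' @seealso [writeMgf()]
#' @export
readMgf <- function(path, defaultCollisionEnergy = 35) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  blockNo <- 0L
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) {
      i <- i + 1L
      next
    }
    if (line != "BEGIN IONS")
      stop("MGF parse error at line ", i, ": expected BEGIN IONS, got '",
           line, "'")
    blockNo <- blockNo + 1L
    pep <- NA_real_
    rt <- NA_real_
    ce <- NA_real_
    title <- sprintf("spectrum_%d", blockNo)
    mzs <- numeric()
    ints <- numeric()
    i <- i + 1L
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (line == "END IONS") {
        closed <- TRUE
        i <- i + 1L
        break
      }
      if (!nzchar(line)) {
        i <- i + 1L
        next
      }
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", line))
        val <- sub("^[^=]*=", "", line)
        if (key == "PEPMASS")
          pep <- as.numeric(strsplit(trimws(val), "[ \t]+")[[1]][1])
        else if (key == "RTINSECONDS") rt <- as.numeric(val)
        else if (key %in% c("COLLISION_ENERGY", "COLLISIONENERGY"))
          ce <- as.numeric(val)
        else if (key == "TITLE") title <- trimws(val)
      } else {
        fields <- strsplit(line, "[ \t]+")[[1]]
        pk <- suppressWarnings(as.numeric(fields[1:2]))
        if (length(fields) < 2L || anyNA(pk))
          stop("MGF parse error at line ", i, ": bad peak line '", line, "'")
        mzs <- c(mzs, pk[1])
        ints <- c(ints, pk[2])
      }
      i <- i + 1L
    }
    if (!closed)
      stop("MGF parse error: BEGIN IONS block starting before line ", i,
           " not terminated by END IONS")
    spectra[[blockNo]] <- MassSpectrum(
      mz = mzs, intensity = ints, precursorMz = pep, rtime = rt,
      collisionEnergy = if (is.na(ce)) defaultCollisionEnergy else ce,
      msLevel = 2L, scanId = title)
  }
  MsRun(spectra = spectra, metadata = list(source = path, format = "mgf"))
}

#' Write a run as a Mascot generic format (MGF) file
#'
#' Writes every spectrum of the run as a `BEGIN IONS` block, m/z and
#' intensity to six decimal places so that a read/write round trip
#' reproduces the peak lists. Peaks are written verbatim (no filtering; use
#' [applyIntensityCutoff()] explicitly).
#'
#' @param run An [MsRun-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readMgf()]
#' @export
writeMgf <- function(run, path) {
  stopifnot(is(run, "MsRun"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra(run)) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", scanId(sp)), con)
    if (!is.na(precursorMz(sp)))
      writeLines(sprintf("PEPMASS=%.6f", precursorMz(sp)), con)
    if (!is.na(rtime(sp)))
      writeLines(sprintf("RTINSECONDS=%.6f", rtime(sp)), con)
    if (!is.na(collisionEnergy(sp)))
      writeLines(sprintf("COLLISION_ENERGY=%g", collisionEnergy(sp)), con)
    if (peaksCount(sp))
      writeLines(sprintf("%.6f %.6f", mz(sp), intensity(sp)), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read the centroided mzML-lite dialect
#'
#' Reads the package's simplified centroided mzML dialect (see
#' [writeMzmlLite()] for the layout): MS1 and MS2 spectra with scan ids,
#' retention times, collision energies and selected-ion (precursor) m/z.
#' Profile-mode spectra are rejected, as the whole workflow assumes
#' centroided data.
#'
#' @param path Path to an mzML-lite XML file.
#' @return An [MsRun-class].
#' @export
readMzmlLite <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "msRunLite")
    stop("unsupported dialect: expected <msRunLite> root, got <",
         xml2::xml_name(doc), ">")
  meta <- list()
  for (node in xml2::xml_find_all(doc, "./metadata"))
    meta[[xml2::xml_attr(node, "key")]] <- xml2::xml_attr(node, "value")
  numOrNA <- function(x) if (is.na(x) || !nzchar(x)) NA_real_ else
    as.numeric(x)
  spectra <- lapply(xml2::xml_find_all(doc, "./spectrum"), function(node) {
    mode <- xml2::xml_attr(node, "mode")
    if (!is.na(mode) && mode != "centroid")
      stop("unsupported dialect: profile-mode spectra are not supported")
    txt <- trimws(xml2::xml_text(xml2::xml_find_first(node, "./peaks")))
    if (nzchar(txt)) {
      pk <- strsplit(strsplit(txt, "[ \t\r\n]+")[[1]], ",", fixed = TRUE)
      mzs <- vapply(pk, function(p) as.numeric(p[1]), numeric(1))
      ints <- vapply(pk, function(p) as.numeric(p[2]), numeric(1))
    } else {
      mzs <- numeric()
      ints <- numeric()
    }
    MassSpectrum(
      mz = mzs, intensity = ints,
      precursorMz = numOrNA(xml2::xml_attr(node, "precursorMz")),
      rtime = numOrNA(xml2::xml_attr(node, "rt")),
      collisionEnergy = numOrNA(xml2::xml_attr(node, "ce")),
      msLevel = as.integer(xml2::xml_attr(node, "msLevel")),
      scanId = xml2::xml_attr(node, "scanId"))
  })
  MsRun(spectra = spectra, metadata = meta)
}

#' Write the centroided mzML-lite dialect
#'
#' Serialises a run as a simplified, self-contained XML dialect carrying the
#' fields the screening workflow needs: per spectrum a `scanId`, `msLevel`,
#' retention time `rt` (s), collision energy `ce` (eV, MS2 only), the
#' selected-ion `precursorMz` (MS2 only), `mode="centroid"`, and the peaks
#' as whitespace-separated `mz,intensity` pairs:
#'
#' ```
#' <msRunLite version="1.0">
#'   <metadata key="sampleId" value="S1"/>
#'   <spectrum scanId="c1_ms1" msLevel="1" rt="0" mode="centroid">
#'     <peaks>310.216600,1500 402.120000,220</peaks>
#'   </spectrum>
#' </msRunLite>
#' ```
#'
#' @param run An [MsRun-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMzmlLite <- function(run, path) {
  stopifnot(is(run, "MsRun"))
  doc <- xml2::xml_new_root("msRunLite", version = "1.0")
  meta <- runMetadata(run)
  for (key in names(meta))
    xml2::xml_add_child(doc, "metadata", key = key,
                        value = as.character(meta[[key]]))
  fmt <- function(x) sprintf("%.6f", x)
  for (sp in spectra(run)) {
    attrs <- list(scanId = scanId(sp), msLevel = as.character(msLevel(sp)),
                  mode = "centroid")
    if (!is.na(rtime(sp))) attrs$rt <- fmt(rtime(sp))
    if (!is.na(collisionEnergy(sp))) attrs$ce <- fmt(collisionEnergy(sp))
    if (!is.na(precursorMz(sp))) attrs$precursorMz <- fmt(precursorMz(sp))
    node <- do.call(xml2::xml_add_child, c(list(doc, "spectrum"), attrs))
    xml2::xml_add_child(node, "peaks",
                        paste(sprintf("%.6f,%.6f", mz(sp), intensity(sp)),
                              collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a run as plain-text (ASCII) peak lists
#'
#' Writes one text file per spectrum into `dir`: a header line
#' `precursor_mz rt ce` followed by tab-separated `mz`/`intensity` rows —
#' the plain-text exchange form consumed by external search tools.
#'
#' @param run An [MsRun-class].
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
exportPeakLists <- function(run, dir) {
  stopifnot(is(run, "MsRun"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sps <- spectra(run)
  paths <- character(length(sps))
  for (k in seq_along(sps)) {
    sp <- sps[[k]]
    id <- gsub("[^A-Za-z0-9._-]", "_", scanId(sp))
    if (!nzchar(id)) id <- sprintf("spectrum_%d", k)
    paths[k] <- file.path(dir, paste0(id, ".txt"))
    con <- file(paths[k], open = "wt")
    writeLines(sprintf("%.6f %.6f %g", precursorMz(sp), rtime(sp),
                       collisionEnergy(sp)), con)
    if (peaksCount(sp))
      writeLines(sprintf("%.6f\t%.6f", mz(sp), intensity(sp)), con)
    close(con)
  }
  invisible(paths)
}
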