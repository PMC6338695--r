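#' Accessor generics
#'
#' Small set of accessor generics shared by the spectrum, run and library
#' classes. All slots are reached through these accessors rather than `@`.
#'
#' @param object An object of one of the package's classes.
#' @param ... Passed on to methods.
#' @return The slot value; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object, ...) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object, ...) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("peaksCount", function(object, ...) standardGeneric("peaksCount"))

#' @rdname accessors
#' @export
setGeneric("precursorMz", function(object, ...) standardGeneric("precursorMz"))

#' @rdname accessors
#' @export
setGeneric("rtime", function(object, ...) standardGeneric("rtime"))

#' @rdname accessors
#' @export
setGeneric("collisionEnergy", function(object, ...)
  standardGeneric("collisionEnergy"))

#' @rdname accessors
#' @export
setGeneric("msLevel", function(object, ...) standardGeneric("msLevel"))

#' @rdname accessors
#' @export
setGeneric("scanId", function(object, ...) standardGeneric("scanId"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(object, ...) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("runMetadata", function(object, ...) standardGeneric("runMetadata"))

#' @rdname accessors
#' @export
setGeneric("compoundId", function(object, ...) standardGeneric("compoundId"))

#' @rdname accessors
#' @export
setGeneric("compoundName", function(object, ...)
  standardGeneric("compoundName"))

#' @rdname accessors
#' @export
setGeneric("logP", function(object, ...) standardGeneric("logP"))

#' @rdname accessors
#' @export
setGeneric("referenceSpectra", function(object, ...)
  standardGeneric("referenceSpectra"))

#' @rdname accessors
#' @export
setGeneric("entries", function(object, ...) standardGeneric("entries"))

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(object, ...) standardGeneric("compoundIds"))
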