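#' Accessors for the core containers
#'
#' `genoCalls()` returns the raw call matrix, `individualInfo()` the
#' individual metadata, `markerInfo()` the marker definition table,
#' `pedRecords()` the pedigree record table.
#'
#' @param x a [ReplicateCalls-class], [GenotypeCalls-class] or
#'   [Pedigree-class] object.
#' @return The underlying matrix or data.frame (a copy; the slots are not
#'   meant to be touched directly).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))

#' @rdname accessors
#' @export
setGeneric("individualInfo", function(x) standardGeneric("individualInfo"))

#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname accessors
#' @export
setGeneric("pedRecords", function(x) standardGeneric("pedRecords"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("sampleType", function(x) standardGeneric("sampleType"))

#' @rdname accessors
#' @export
setMethod("genoCalls", "ReplicateCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("genoCalls", "GenotypeCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("individualInfo", "GenotypeCalls", function(x) x@individuals)

#' @rdname accessors
#' @export
setMethod("markerInfo", "GenotypeCalls", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("pedRecords", "Pedigree", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("sampleId", "ReplicateCalls", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleType", "ReplicateCalls", function(x) x@sampleType)
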