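#' Accessor generics
#'
#' Small family of accessor generics for the package's S4 classes.
#' Accessors are preferred over direct slot access (`@`) throughout.
#'
#' @param x,object an object of one of the package's S4 classes.
#' @param value replacement value.
#' @param ... passed to methods.
#' @return the slot value (see the class documentation for types).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("codedValues", function(x) standardGeneric("codedValues"))

#' @rdname accessors
#' @export
setGeneric("uncodedValues", function(x) standardGeneric("uncodedValues"))

#' @rdname accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname accessors
#' @export
setGeneric("responses<-", function(x, value) standardGeneric("responses<-"))

#' @rdname accessors
#' @export
setGeneric("designRoles", function(x) standardGeneric("designRoles"))

#' @rdname accessors
#' @export
setGeneric("factorSpecs", function(x) standardGeneric("factorSpecs"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("peakId", function(x) standardGeneric("peakId"))

#' @rdname accessors
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname accessors
#' @export
setGeneric("uvLambdaMax", function(x) standardGeneric("uvLambdaMax"))

#' @rdname accessors
#' @export
setGeneric("retentionTime", function(x) standardGeneric("retentionTime"))

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("compoundName", function(x) standardGeneric("compoundName"))

#' @rdname accessors
#' @export
setGeneric("compoundClass", function(x) standardGeneric("compoundClass"))

#' @rdname accessors
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))

#' @rdname accessors
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))
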