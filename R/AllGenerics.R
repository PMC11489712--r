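#' @include AllClasses.R
NULL

#' Accessor generics for key objects
#'
#' Slot access throughout the package goes through accessors so the internal
#' representation can evolve without breaking callers.
#'
#' @param x A \linkS4class{Key}, \linkS4class{Couplet}, or
#'   \linkS4class{Lead} as appropriate.
#' @name key-accessors
NULL

#' @rdname key-accessors
#' @export
setGeneric("keyId", function(x) standardGeneric("keyId"))

#' @rdname key-accessors
#' @export
setGeneric("keyTitle", function(x) standardGeneric("keyTitle"))

#' @rdname key-accessors
#' @export
setGeneric("keyStyle", function(x) standardGeneric("keyStyle"))

#' @rdname key-accessors
#' @export
setGeneric("keyScope", function(x) standardGeneric("keyScope"))

#' @rdname key-accessors
#' @export
setGeneric("couplets", function(x) standardGeneric("couplets"))

#' @rdname key-accessors
#' @export
setGeneric("coupletNumber", function(x) standardGeneric("coupletNumber"))

#' @rdname key-accessors
#' @export
setGeneric("retraceRef", function(x) standardGeneric("retraceRef"))

#' @rdname key-accessors
#' @export
setGeneric("leads", function(x) standardGeneric("leads"))

#' @rdname key-accessors
#' @export
setGeneric("leadFeatures", function(x) standardGeneric("leadFeatures"))

#' @rdname key-accessors
#' @export
setGeneric("leadTarget", function(x) standardGeneric("leadTarget"))

#' @rdname key-accessors
#' @export
setGeneric("figureRefs", function(x) standardGeneric("figureRefs"))

#' Taxa named by a key
#'
#' @param x A \linkS4class{Key}.
#' @return Character vector of distinct terminal taxon names (first printed
#'   spelling of each), in order of first appearance.
#' @export
setGeneric("keyTaxa", function(x) standardGeneric("keyTaxa"))

#' Rubric verdict accessors
#'
#' @param x A \linkS4class{RubricResult}.
#' @name rubric-accessors
NULL

#' @rdname rubric-accessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))

#' @rdname rubric-accessors
#' @export
setGeneric("nSuboptimal", function(x) standardGeneric("nSuboptimal"))

#' @rdname rubric-accessors
#' @export
setGeneric("nApplicable", function(x) standardGeneric("nApplicable"))

#' @rdname rubric-accessors
#' @export
setGeneric("pctSuboptimal", function(x) standardGeneric("pctSuboptimal"))
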