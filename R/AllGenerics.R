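#' @include AllClasses.R
NULL

#' Accessors for DEMcluster data classes
#'
#' `cancers()` and `mirnas()` list the cancer types / mature miRNA ids known
#' to an object; `demCalls()` returns the call table of a
#' [DEMCallSet-class]; `directionMatrix()` the character matrix backing a
#' [DEMMatrix-class]; `clusterIds()`, `clusterMembers()` and
#' `clusterSpans()` expose a [ClusterSet-class].
#'
#' @param x a DEMcluster data object.
#' @return `cancers()`, `mirnas()`, `clusterIds()`: character vectors.
#'   `demCalls()`: a `DataFrame`. `directionMatrix()`: a character matrix.
#'   `clusterMembers()`: a named list. `clusterSpans()`: a `GRanges`.
#' @name accessors
#' @aliases cancers mirnas demCalls directionMatrix clusterIds
#'   clusterMembers clusterSpans
NULL

#' @rdname accessors
#' @export
setGeneric("cancers", function(x) standardGeneric("cancers"))

#' @rdname accessors
#' @export
setGeneric("mirnas", function(x) standardGeneric("mirnas"))

#' @rdname accessors
#' @export
setGeneric("demCalls", function(x) standardGeneric("demCalls"))

#' @rdname accessors
#' @export
setGeneric("directionMatrix", function(x) standardGeneric("directionMatrix"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("clusterSpans", function(x) standardGeneric("clusterSpans"))

#' Consolidate experiment-level calls into a per-cancer matrix
#'
#' @param x a [DEMCallSet-class].
#' @param policy consolidation policy; only `"majority"` is defined.
#' @param ... further arguments for methods.
#' @return a [DEMMatrix-class].
#' @export
setGeneric("consolidate", function(x, policy = "majority", ...)
    standardGeneric("consolidate"))
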