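#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' DEMCallSet: experiment-level differential-expression calls
#'
#' A `DEMCallSet` holds one record per (miRNA, cancer type, experiment)
#' combination, each carrying an UP/DOWN direction and, optionally, the
#' log2 fold change and FDR reported by the upstream differential-expression
#' analysis. It is the raw-input container of the package; all statistics
#' operate on the consolidated [DEMMatrix-class].
#'
#' @slot calls a [S4Vectors::DataFrame] with columns `mature_id`, `cancer`,
#'   `experiment_id`, `direction` (values `"UP"`/`"DOWN"`), `log2fc`, `fdr`.
#'
#' @seealso [readDEMTable()], [consolidate()]
#' @export
setClass("DEMCallSet", slots = c(calls = "DataFrame"))

setValidity("DEMCallSet", function(object) {
    df <- object@calls
    need <- c("mature_id", "cancer", "experiment_id", "direction")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        return(paste("missing call columns:", paste(miss, collapse = ", ")))
    if (nrow(df)) {
        if (!all(df$direction %in% c("UP", "DOWN")))
            return("direction must be 'UP' or 'DOWN'")
        if (any(!nzchar(df$mature_id)))
            return("mature_id must be non-empty")
        key <- paste(df$mature_id, df$cancer, df$experiment_id, sep = "\r")
        if (anyDuplicated(key))
            return("duplicate (miRNA, cancer, experiment) records")
    }
    TRUE
})

#' DEMMatrix: consolidated per-cancer direction calls
#'
#' The unit of all downstream statistics: one direction call (`"UP"`,
#' `"DOWN"`, or `NA` for "not associated") per (miRNA, cancer type) pair.
#' Rows are the miRNA universe, columns are cancer types.
#'
#' @slot mat character matrix, rows = mature miRNA ids, columns = cancer
#'   types; entries in `{"UP","DOWN",NA}`.
#' @slot provenance character scalar recording the consolidation policy
#'   (or generator) that produced the matrix.
#'
#' @seealso [consolidate()], [homogeneityTest()], [enrichmentProfile()]
#' @export
setClass("DEMMatrix", slots = c(mat = "matrix", provenance = "character"))

setValidity("DEMMatrix", function(object) {
    m <- object@mat
    if (!is.character(m))
        return("direction matrix must be character")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("direction matrix must carry miRNA rownames and cancer colnames")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        return("duplicated miRNA or cancer names")
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% c("UP", "DOWN")))
        return("entries must be 'UP', 'DOWN' or NA")
    TRUE
})

#' ClusterSet: genomic miRNA cluster membership
#'
#' Maps cluster identifiers to ordered member miRNA ids (precursor ids right
#' after [callClusters()], mature ids after [mapMature()] or
#' [readClusterTable()]). Genomic spans are carried as a named
#' [GenomicRanges::GRanges] when coordinate provenance exists; an empty
#' `GRanges` otherwise.
#'
#' @slot members named list, cluster id -> character vector of member ids
#'   (each cluster has at least 2 members; no id belongs to two clusters).
#' @slot span `GRanges` named by cluster id (possibly empty).
#' @slot metadata list of provenance details; [callClusters()] stores the
#'   non-clustered singleton ids under `$singletons`.
#'
#' @export
setClass("ClusterSet",
    slots = c(members = "list", span = "GRanges", metadata = "list"))

setValidity("ClusterSet", function(object) {
    mem <- object@members
    if (length(mem)) {
        if (is.null(names(mem)) || any(!nzchar(names(mem))))
            return("clusters must be named")
        if (anyDuplicated(names(mem)))
            return("duplicated cluster ids")
        sizes <- lengths(mem)
        if (any(sizes < 2L))
            return("every cluster must have >= 2 members")
        all_ids <- unlist(mem, use.names = FALSE)
        if (anyDuplicated(all_ids))
            return("a miRNA id appears in more than one cluster")
    }
    sp <- object@span
    if (length(sp) && !all(names(sp) %in% names(mem)))
        return("span names must be cluster ids")
    TRUE
})

#' AliasTable: miRBase accession-to-names history
#'
#' One record per miRBase accession, listing every name the accession has
#' carried; the last name is the current one. Used by [convertIDs()] to
#' update identifiers from older miRBase releases.
#'
#' @slot records named list, accession -> character vector of names
#'   (chronological; last = current).
#' @export
setClass("AliasTable", slots = c(records = "list"))

setValidity("AliasTable", function(object) {
    r <- object@records
    if (length(r)) {
        if (is.null(names(r)) || any(!nzchar(names(r))))
            return("records must be named by accession")
        if (any(lengths(r) < 1L))
            return("every accession needs at least one name")
        if (!all(vapply(r, is.character, logical(1))))
            return("names must be character vectors")
    }
    TRUE
})

#' SimConfig: synthetic DEM generator settings
#'
#' Bundle of generator parameters; see [simConfig()] for defaults and
#' [simulateDEM()] for the generative model.
#'
#' @slot nMirnas size of the miRNA universe.
#' @slot fracClustered fraction of the universe placed into clusters.
#' @slot meanClusterSize mean of the truncated-geometric cluster size law.
#' @slot minClusterSize smallest cluster size permitted (>= 2).
#' @slot nCancers number of cancer types simulated.
#' @slot pAssoc per-cancer probability that a miRNA is a DEM.
#' @slot pUp probability an independent direction draw is UP.
#' @slot rho co-direction probability: a clustered DEM copies its cluster's
#'   per-cancer consensus direction with probability `rho`.
#' @slot seed integer seed driving the single RNG stream of one
#'   [simulateDEM()] call.
#' @export
setClass("SimConfig", slots = c(
    nMirnas = "integer", fracClustered = "numeric",
    meanClusterSize = "numeric", minClusterSize = "integer",
    nCancers = "integer", pAssoc = "numeric", pUp = "numeric",
    rho = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    p <- c(object@fracClustered, object@pAssoc, object@pUp, object@rho)
    if (any(p < 0) || any(p > 1))
        return("fracClustered, pAssoc, pUp and rho must lie in [0, 1]")
    if (object@nMirnas < 2L) return("nMirnas must be >= 2")
    if (object@nCancers < 1L) return("nCancers must be >= 1")
    if (object@minClusterSize < 2L) return("minClusterSize must be >= 2")
    if (object@meanClusterSize < object@minClusterSize)
        return("meanClusterSize must be >= minClusterSize")
    TRUE
})

#' HomogeneityPolicy: conventions for the cluster homogeneity statistic
#'
#' See [homogeneityPolicy()] for the meaning and defaults of each field.
#'
#' @slot minMembersPerCancer minimum direction-called members for a cancer
#'   to count as eligible for a cluster.
#' @slot tieIsHomogeneous whether an exact UP/DOWN tie counts as homogeneous.
#' @slot exceedance p-value rule: `"strict"`, `"weak"`, or `"add_one"`.
#' @slot nPerm number of permutation replicates.
#' @export
setClass("HomogeneityPolicy", slots = c(
    minMembersPerCancer = "integer", tieIsHomogeneous = "logical",
    exceedance = "character", nPerm = "integer"))

setValidity("HomogeneityPolicy", function(object) {
    if (object@nPerm < 1L) return("nPerm must be >= 1")
    if (!object@exceedance %in% c("strict", "weak", "add_one"))
        return("exceedance must be 'strict', 'weak' or 'add_one'")
    if (object@minMembersPerCancer < 1L)
        return("minMembersPerCancer must be >= 1")
    TRUE
})
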