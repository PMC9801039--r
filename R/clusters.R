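#' @include AllGenerics.R
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

#' Construct a ClusterSet
#'
#' @param members named list mapping cluster id to a character vector of
#'   member miRNA ids (>= 2 per cluster, no id in two clusters).
#' @param span optional `GRanges` of cluster genomic spans, named by
#'   cluster id.
#' @param metadata optional list of provenance details.
#' @return a [ClusterSet-class].
#' @export
ClusterSet <- function(members = list(), span = GenomicRanges::GRanges(),
                       metadata = list()) {
    new("ClusterSet", members = members, span = span, metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("clusterIds", "ClusterSet", function(x) names(x@members))

#' @rdname accessors
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("clusterSpans", "ClusterSet", function(x) x@span)

#' @rdname accessors
#' @export
setMethod("mirnas", "ClusterSet",
          function(x) unlist(x@members, use.names = FALSE))

setMethod("show", "ClusterSet", function(object) {
    sz <- lengths(object@members)
    cat("ClusterSet with", length(sz), "clusters |",
        sum(sz), "member miRNAs")
    if (length(sz)) cat(" | sizes ", min(sz), "-", max(sz), sep = "")
    cat("\n")
})

#' Read miRBase-style miRNA annotation (GFF3)
#'
#' Imports a miRBase genome annotation and splits it into precursor
#' (`miRNA_primary_transcript`) and mature (`miRNA`) records, resolving each
#' mature record's `Derives_from` accession to its precursor's name.
#'
#' @param path path to the GFF3 file.
#' @return a list with elements `precursors` (a `GRanges` named by precursor
#'   name) and `matures` (a `GRanges` with metadata columns `mature_id` and
#'   `precursor_id`).
#' @export
readMirnaGFF <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    pre <- gr[gr$type == "miRNA_primary_transcript"]
    mat <- gr[gr$type == "miRNA"]
    names(pre) <- pre$Name
    df <- pre$ID
    # Derives_from may import as character or CharacterList
    d <- mat$Derives_from
    if (is(d, "List")) d <- vapply(d, function(v)
        if (length(v)) v[[1]] else NA_character_, character(1))
    mat$mature_id <- mat$Name
    mat$precursor_id <- pre$Name[match(d, df)]
    unk <- is.na(mat$precursor_id)
    if (any(unk)) {
        warning(sum(unk), " mature record(s) reference unknown precursors; ",
                "skipped")
        mat <- mat[!unk]
    }
    list(precursors = pre, matures = mat)
}

#' Identify miRNA clusters from precursor coordinates
#'
#' Precursors on the same chromosome are chained greedily in coordinate
#' order while the gap between consecutive precursor intervals is at most
#' `maxGap` base pairs. Strand never splits a chain: clusters may contain
#' members in the same or opposite orientation. Optionally a chain is broken
#' where another transcriptional unit lies wholly between two consecutive
#' precursors. Chains of two or more precursors become clusters; the
#' remaining singleton ids are stored in `metadata(x)$singletons`.
#'
#' The gap between intervals `[s1,e1]` and `[s2,e2]` (1-based inclusive,
#' `s2 >= s1`) is `s2 - e1 - 1`; overlapping or bookended precursors have
#' gap <= 0 and always chain. Within a growing chain the gap (and the
#' interruption window) is measured from the rightmost end seen so far, so
#' the greedy sweep returns exactly the connected components of the
#' pairwise gap-<=-maxGap graph.
#'
#' @param records precursor annotation: a `GRanges` named by precursor id
#'   (as returned in `readMirnaGFF()$precursors`).
#' @param maxGap maximum inter-precursor gap in bp (default 10000, the
#'   conventional inter-miRNA distance cutoff for cluster catalogues).
#' @param interruptions optional `GRanges` of other transcriptional units;
#'   ignored unless `respectInterruptions` is `TRUE`.
#' @param respectInterruptions whether to break chains across interruption
#'   intervals; defaults to `TRUE` when `interruptions` is supplied.
#' @return a [ClusterSet-class] over precursor ids, with genomic spans.
#' @examples
#' gr <- GenomicRanges::GRanges("chr17", IRanges::IRanges(
#'     start = c(100, 6000), width = 80), strand = c("+", "-"))
#' names(gr) <- c("mir-a", "mir-b")
#' callClusters(gr, maxGap = 10000)
#' @export
callClusters <- function(records, maxGap = 10000L, interruptions = NULL,
                         respectInterruptions = !is.null(interruptions)) {
    stopifnot(is(records, "GRanges"), maxGap >= 0)
    if (is.null(names(records)) || any(!nzchar(names(records))))
        stop("precursor records must be named")
    if (anyDuplicated(names(records)))
        stop("duplicated precursor ids: ",
             paste(unique(names(records)[duplicated(names(records))]),
                   collapse = ", "))
    ord <- order(as.character(seqnames(records)), start(records),
                 end(records))
    records <- records[ord]
    chrom <- as.character(seqnames(records))
    s <- start(records); e <- end(records)
    n <- length(records)
    chain <- integer(n)
    if (n) {
        chain[1L] <- 1L
        runEnd <- e[1L]   # rightmost end of the current chain
        for (k in seq_len(n - 1L)) {
            brk <- chrom[k + 1L] != chrom[k] ||
                (s[k + 1L] - runEnd - 1L) > maxGap
            if (!brk && respectInterruptions && length(interruptions)) {
                ic <- as.character(seqnames(interruptions)) == chrom[k] &
                    start(interruptions) > runEnd &
                    end(interruptions) < s[k + 1L]
                brk <- any(ic)
            }
            chain[k + 1L] <- chain[k] + as.integer(brk)
            runEnd <- if (brk) e[k + 1L] else max(runEnd, e[k + 1L])
        }
    }
    sizes <- tabulate(chain)
    keep <- which(sizes >= 2L)
    members <- list()
    span <- GenomicRanges::GRanges()
    if (length(keep)) {
        ids <- sprintf("CL%04d", seq_along(keep))
        members <- lapply(keep, function(g) names(records)[chain == g])
        names(members) <- ids
        span <- GenomicRanges::GRanges(
            seqnames = vapply(keep, function(g) chrom[chain == g][1L],
                              character(1)),
            ranges = IRanges::IRanges(
                start = vapply(keep, function(g) min(s[chain == g]),
                               integer(1)),
                end = vapply(keep, function(g) max(e[chain == g]),
                             integer(1))))
        names(span) <- ids
    }
    singles <- names(records)[chain %in% which(sizes == 1L)]
    new("ClusterSet", members = members, span = span,
        metadata = list(singletons = singles, maxGap = maxGap,
                        respectInterruptions = respectInterruptions))
}

#' Expand precursor clusters to mature miRNA membership
#'
#' Each precursor cluster is replaced by the union of the mature miRNAs
#' deriving from its precursors (both arms kept as distinct members).
#' Clusters whose mature expansion has fewer than two ids are dropped.
#'
#' @param clusters a [ClusterSet-class] over precursor ids.
#' @param matures mature annotation: a `GRanges` (or data.frame) with
#'   columns `mature_id` and `precursor_id`, as returned in
#'   `readMirnaGFF()$matures`.
#' @return a [ClusterSet-class] over mature ids (spans carried over).
#' @export
mapMature <- function(clusters, matures) {
    stopifnot(is(clusters, "ClusterSet"))
    md <- if (is(matures, "GRanges")) as.data.frame(matures@elementMetadata)
          else as.data.frame(matures)
    stopifnot(all(c("mature_id", "precursor_id") %in% colnames(md)))
    known <- unlist(clusters@members, use.names = FALSE)
    members <- lapply(clusters@members, function(pre) {
        unique(md$mature_id[md$precursor_id %in% pre])
    })
    keep <- lengths(members) >= 2L
    if (any(!keep))
        message("mapMature: dropping ", sum(!keep),
                " cluster(s) with < 2 mature members")
    span <- clusters@span
    span <- span[names(span) %in% names(members)[keep]]
    new("ClusterSet", members = members[keep], span = span,
        metadata = clusters@metadata)
}

#' Read / write precomputed cluster membership tables
#'
#' The TSV dialect has columns `cluster_id` and `mirna_id`, one row per
#' member. On reading, groups with fewer than two members are rejected with
#' a warning; a miRNA listed under two clusters is an error. An empty table
#' yields an empty [ClusterSet-class].
#'
#' @param path file path.
#' @return `readClusterTable`: a [ClusterSet-class];
#'   `writeClusterTable`: `path` invisibly.
#' @export
readClusterTable <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    stopifnot(all(c("cluster_id", "mirna_id") %in% colnames(df)))
    if (!nrow(df)) return(ClusterSet())
    dup <- !duplicated(df[c("cluster_id", "mirna_id")])
    df <- df[dup, , drop = FALSE]
    amb <- unique(df$mirna_id[duplicated(df$mirna_id)])
    if (length(amb))
        stop("miRNA(s) listed under more than one cluster: ",
             paste(amb, collapse = ", "))
    members <- split(df$mirna_id, df$cluster_id)
    small <- lengths(members) < 2L
    if (any(small)) {
        warning("dropping ", sum(small),
                " cluster group(s) with < 2 members: ",
                paste(names(members)[small], collapse = ", "))
        members <- members[!small]
    }
    ClusterSet(members = as.list(members))
}

#' @rdname readClusterTable
#' @param x a [ClusterSet-class].
#' @export
writeClusterTable <- function(x, path) {
    stopifnot(is(x, "ClusterSet"))
    mem <- clusterMembers(x)
    df <- data.frame(cluster_id = rep(names(mem), lengths(mem)),
                     mirna_id = unlist(mem, use.names = FALSE))
    .writeTSV(df, path)
}

#' Export cluster genomic spans as BED
#'
#' Writes one BED record (0-based half-open, converted from the 1-based
#' inclusive coordinates held internally) per cluster with genomic
#' provenance.
#'
#' @param x a [ClusterSet-class] with non-empty spans.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeClusterBED <- function(x, path) {
    stopifnot(is(x, "ClusterSet"))
    sp <- clusterSpans(x)
    if (!length(sp)) stop("ClusterSet carries no genomic spans")
    sp$name <- names(sp)
    rtracklayer::export(sp, path, format = "BED")
    invisible(path)
}
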