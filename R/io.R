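#' @include AllGenerics.R
NULL

#' Construct a DEMCallSet from a call table
#'
#' @param calls a `data.frame` or `DataFrame` with columns `mature_id`,
#'   `cancer`, `experiment_id`, `direction` and optionally `log2fc`, `fdr`.
#' @return a [DEMCallSet-class].
#' @examples
#' cs <- DEMCallSet(data.frame(
#'     mature_id = c("hsa-miR-21-5p", "hsa-miR-145-5p"),
#'     cancer = "BRCA", experiment_id = "E1",
#'     direction = c("UP", "DOWN")))
#' cancers(cs)
#' @export
DEMCallSet <- function(calls) {
    df <- DataFrame(calls)
    if (is.null(df$log2fc)) df$log2fc <- NA_real_
    if (is.null(df$fdr)) df$fdr <- NA_real_
    df$direction <- toupper(as.character(df$direction))
    for (col in c("mature_id", "cancer", "experiment_id"))
        if (!is.null(df[[col]])) df[[col]] <- as.character(df[[col]])
    new("DEMCallSet", calls = df)
}

#' @rdname accessors
#' @export
setMethod("demCalls", "DEMCallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("cancers", "DEMCallSet", function(x) sort(unique(x@calls$cancer)))

#' @rdname accessors
#' @export
setMethod("mirnas", "DEMCallSet", function(x) sort(unique(x@calls$mature_id)))

setMethod("show", "DEMCallSet", function(object) {
    cat("DEMCallSet with", nrow(object@calls), "calls |",
        length(mirnas(object)), "miRNAs |",
        length(cancers(object)), "cancer types\n")
})

#' Read a DEM call table
#'
#' Reads a tab-separated table of experiment-level differential-expression
#' calls. Required columns: `mirna_id`, `cancer_type`, `experiment_id`,
#' `direction`; optional: `log2fc`, `fdr`. Direction strings are accepted
#' case-insensitively (`up`, `Up`, `UP`, ...). Lines starting with `#` are
#' skipped.
#'
#' @param path path to the TSV file.
#' @return a [DEMCallSet-class].
#' @seealso [writeDEMTable()], [consolidate()]
#' @export
readDEMTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("mirna_id", "cancer_type", "experiment_id", "direction")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("DEM table is missing required column(s): ",
             paste(miss, collapse = ", "))
    dir <- toupper(trimws(df$direction))
    bad <- which(!dir %in% c("UP", "DOWN"))
    if (length(bad))
        stop("invalid direction '", df$direction[bad[1]],
             "' at data row ", bad[1], " (expected UP or DOWN)")
    calls <- DataFrame(mature_id = df$mirna_id, cancer = df$cancer_type,
                       experiment_id = df$experiment_id, direction = dir)
    calls$log2fc <- if (is.null(df$log2fc)) NA_real_ else
        suppressWarnings(as.numeric(df$log2fc))
    calls$fdr <- if (is.null(df$fdr)) NA_real_ else
        suppressWarnings(as.numeric(df$fdr))
    dup <- which(duplicated(.callKey(calls)))
    if (length(dup))
        stop("duplicate (miRNA, cancer, experiment) record at data row ",
             dup[1], ": ", calls$mature_id[dup[1]], " / ",
             calls$cancer[dup[1]], " / ", calls$experiment_id[dup[1]])
    new("DEMCallSet", calls = calls)
}

#' Write a DEM call table
#'
#' Inverse of [readDEMTable()]: writes the TSV dialect that reader consumes,
#' so a read/write round trip preserves the call multiset.
#'
#' @param x a [DEMCallSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDEMTable <- function(x, path) {
    stopifnot(is(x, "DEMCallSet"))
    df <- as.data.frame(x@calls)
    out <- data.frame(mirna_id = df$mature_id, cancer_type = df$cancer,
                      experiment_id = df$experiment_id,
                      direction = df$direction,
                      log2fc = df$log2fc, fdr = df$fdr)
    .writeTSV(out, path)
}

#' Build a DEMMatrix directly from per-(cancer, miRNA) directions
#'
#' @param mat character matrix of `"UP"`/`"DOWN"`/`NA`, rows = miRNAs,
#'   columns = cancer types.
#' @param provenance free-text provenance tag.
#' @return a [DEMMatrix-class].
#' @export
DEMMatrix <- function(mat, provenance = "direct") {
    new("DEMMatrix", mat = mat, provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("directionMatrix", "DEMMatrix", function(x) x@mat)

#' @rdname accessors
#' @export
setMethod("cancers", "DEMMatrix", function(x) colnames(x@mat))

#' @rdname accessors
#' @export
setMethod("mirnas", "DEMMatrix", function(x) rownames(x@mat))

setMethod("show", "DEMMatrix", function(object) {
    m <- object@mat
    cat("DEMMatrix:", nrow(m), "miRNAs x", ncol(m), "cancer types |",
        sum(!is.na(m)), "associations | provenance:",
        object@provenance, "\n")
})

#' @describeIn consolidate Majority vote over experiments within each
#'   (cancer, miRNA); exact ties carry no direction and are dropped (with a
#'   message). With one experiment per cancer this is a lossless relabeling.
#' @export
setMethod("consolidate", "DEMCallSet", function(x, policy = "majority", ...) {
    policy <- match.arg(policy, "majority")
    df <- x@calls
    mir <- sort(unique(df$mature_id))
    can <- sort(unique(df$cancer))
    mat <- matrix(NA_character_, length(mir), length(can),
                  dimnames = list(mir, can))
    if (nrow(df)) {
        i <- match(df$mature_id, mir)
        j <- match(df$cancer, can)
        up <- as.integer(df$direction == "UP")
        cell <- (j - 1L) * length(mir) + i
        nUp <- rowsum(up, cell)
        nTot <- rowsum(rep(1L, length(cell)), cell)
        idx <- as.integer(rownames(nUp))
        nDown <- nTot - nUp
        dirs <- ifelse(nUp > nDown, "UP",
                       ifelse(nDown > nUp, "DOWN", NA_character_))
        nTies <- sum(is.na(dirs))
        if (nTies)
            message("consolidate: dropping ", nTies,
                    " (cancer, miRNA) pair(s) with tied UP/DOWN votes")
        mat[idx] <- dirs
    }
    new("DEMMatrix", mat = mat, provenance = "majority")
})

#' Write / read a consolidated DEM matrix
#'
#' Serialized as a long TSV (`cancer_type`, `mirna_id`, `direction`), one
#' row per association; the full miRNA universe (rows that may have no
#' association anywhere) is preserved through a `# universe:` header
#' comment.
#'
#' @param x a [DEMMatrix-class].
#' @param path file path.
#' @return `writeDEMMatrix`: `path` invisibly; `readDEMMatrix`: a
#'   [DEMMatrix-class].
#' @export
writeDEMMatrix <- function(x, path) {
    stopifnot(is(x, "DEMMatrix"))
    m <- x@mat
    idx <- which(!is.na(m), arr.ind = TRUE)
    idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# universe: ", paste(rownames(m), collapse = ",")),
                 paste0("# cancers: ", paste(colnames(m), collapse = ",")),
                 paste0("# provenance: ", x@provenance),
                 "cancer_type\tmirna_id\tdirection"), con)
    if (nrow(idx))
        writeLines(paste(colnames(m)[idx[, 2L]], rownames(m)[idx[, 1L]],
                         m[idx], sep = "\t"), con)
    invisible(path)
}

#' @rdname writeDEMMatrix
#' @export
readDEMMatrix <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    .field <- function(tag) {
        ln <- grep(paste0("^# ", tag, ": "), hdr, value = TRUE)
        if (!length(ln)) return(character())
        strsplit(sub(paste0("^# ", tag, ": "), "", ln[1]), ",",
                 fixed = TRUE)[[1]]
    }
    df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    mir <- .field("universe")
    can <- .field("cancers")
    if (!length(mir)) mir <- sort(unique(df$mirna_id))
    if (!length(can)) can <- sort(unique(df$cancer_type))
    prov <- .field("provenance")
    mat <- matrix(NA_character_, length(mir), length(can),
                  dimnames = list(mir, can))
    if (nrow(df))
        mat[cbind(match(df$mirna_id, mir), match(df$cancer_type, can))] <-
            toupper(df$direction)
    new("DEMMatrix", mat = mat,
        provenance = if (length(prov)) paste(prov, collapse = ",") else "file")
}

#' Read a miRBase-style alias table
#'
#' One record per line: accession, a tab, then the semicolon-separated list
#' of names the accession has carried (a trailing semicolon is tolerated).
#' The last name is the current one.
#'
#' @param path path to the aliases file.
#' @return an [AliasTable-class].
#' @export
readAliasTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
        stop("malformed alias line ", bad[1], ": expected <accession>\\t<names>")
    acc <- vapply(parts, `[[`, character(1), 1L)
    names_ <- lapply(parts, function(p) {
        nm <- strsplit(p[[2L]], ";", fixed = TRUE)[[1]]
        nm <- trimws(nm)
        nm[nzchar(nm)]
    })
    if (anyDuplicated(acc))
        stop("duplicated accession in alias table: ", acc[duplicated(acc)][1])
    names(names_) <- acc
    new("AliasTable", records = names_)
}

#' Convert miRNA identifiers to their current miRBase names
#'
#' Each query id is looked up among all names ever carried by any accession;
#' a hit maps to the last (current) name of that accession. Ids found under
#' two different accessions raise an ambiguity error; ids matching no alias
#' are flagged unmapped (`current_id` = `NA`).
#'
#' @param ids character vector of miRNA names to convert.
#' @param aliases an [AliasTable-class].
#' @return a `DataFrame` with columns `input_id`, `accession`, `current_id`,
#'   `mapped`, one row per input in input order.
#' @examples
#' at <- new("AliasTable", records = list(
#'     MIMAT0000433 = c("hsa-miR-142-3p", "hsa-miR-142-3p.1",
#'                      "hsa-miR-142-3p")))
#' convertIDs("hsa-miR-142-3p.1", at)$current_id
#' @export
convertIDs <- function(ids, aliases) {
    stopifnot(is(aliases, "AliasTable"))
    rec <- aliases@records
    lut <- data.frame(
        name = unlist(rec, use.names = FALSE),
        accession = rep(names(rec), lengths(rec)),
        stringsAsFactors = FALSE)
    lut <- unique(lut)
    out <- DataFrame(input_id = as.character(ids),
                     accession = NA_character_,
                     current_id = NA_character_,
                     mapped = FALSE)
    for (k in seq_along(ids)) {
        hits <- unique(lut$accession[lut$name == ids[[k]]])
        if (length(hits) > 1L)
            stop("ambiguous id '", ids[[k]], "': found under accessions ",
                 paste(hits, collapse = " and "))
        if (length(hits) == 1L) {
            nm <- rec[[hits]]
            out$accession[k] <- hits
            out$current_id[k] <- nm[length(nm)]
            out$mapped[k] <- TRUE
        }
    }
    out
}
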