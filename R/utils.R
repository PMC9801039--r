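# Run code under a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()),
                    add = TRUE)
        } else {
            on.exit(suppressWarnings(
                rm(".Random.seed", envir = globalenv())), add = TRUE)
        }
        set.seed(as.integer(seed))
    }
    force(code)
}

.writeTSV <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

# key used to detect duplicate call records
.callKey <- function(df) paste(df$mature_id, df$cancer, df$experiment_id,
                               sep = "\r")
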