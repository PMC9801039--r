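#' @include AllGenerics.R
NULL

#' Vote-counting consistency scores for DEM meta-profiling
#'
#' For each miRNA (within each cancer type, or pooled pan-cancer) the
#' experiments calling it a DEM are tallied into `n_up` and `n_down`, and
#' the consistent score is the net directional support
#' `score = (n_up - n_down) / n_total`, ranging from -1 (unanimously
#' down-regulated) through 0 (balanced) to +1 (unanimously up-regulated).
#' `n_total` counts the experiments reporting the miRNA as a DEM —
#' experiments that tested but did not call it cannot be known from call
#' tables — so `n_total = n_up + n_down` and the supporting-experiment
#' count `n_support = max(n_up, n_down)` is also reported for classical
#' vote-counting rankings.
#'
#' @param calls a [DEMCallSet-class].
#' @param scope `"per_cancer"` (default) or `"pan_cancer"` (the cancer
#'   column is then `"pan-cancer"` and experiments pool across cancers).
#' @param minExperiments drop records backed by fewer than this many
#'   experiments (default 1).
#' @return a `DataFrame` with columns `mature_id`, `cancer`, `n_up`,
#'   `n_down`, `n_total`, `n_support`, `score`, sorted by decreasing
#'   `|score|` then decreasing `n_total`.
#' @examples
#' cs <- DEMCallSet(data.frame(
#'     mature_id = "hsa-miR-21-5p", cancer = "BRCA",
#'     experiment_id = c("E1", "E2", "E3"),
#'     direction = c("UP", "UP", "DOWN")))
#' consistencyScores(cs)$score   # (2 - 1) / 3
#' @export
consistencyScores <- function(calls, scope = c("per_cancer", "pan_cancer"),
                              minExperiments = 1L) {
    stopifnot(is(calls, "DEMCallSet"))
    scope <- match.arg(scope)
    df <- as.data.frame(calls@calls)
    if (!nrow(df))
        return(DataFrame(mature_id = character(), cancer = character(),
                         n_up = integer(), n_down = integer(),
                         n_total = integer(), n_support = integer(),
                         score = numeric()))
    grpCancer <- if (scope == "per_cancer") df$cancer else "pan-cancer"
    key <- paste(df$mature_id, grpCancer, sep = "\r")
    up <- as.integer(df$direction == "UP")
    nUp <- rowsum(up, key)
    nTot <- rowsum(rep(1L, nrow(df)), key)
    keys <- rownames(nUp)
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    nUp <- as.integer(nUp)
    nTot <- as.integer(nTot)
    nDown <- nTot - nUp
    res <- DataFrame(mature_id = parts[, 1L], cancer = parts[, 2L],
                     n_up = nUp, n_down = nDown, n_total = nTot,
                     n_support = pmax(nUp, nDown),
                     score = (nUp - nDown) / nTot)
    res <- res[res$n_total >= minExperiments, ]
    res[order(-abs(res$score), -res$n_total, res$mature_id), ]
}
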