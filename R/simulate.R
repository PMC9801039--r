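#' @include AllClasses.R
NULL

#' Synthetic DEM generator configuration
#'
#' The defaults emulate the human miRNA landscape the package's statistics
#' are designed for: a universe of 1588 cancer-associated mature miRNAs of
#' which 688 (43.3%) fall into genomic clusters, 19 cancer types, a near-even
#' direction balance (48% up-regulated, matching large breast-cancer DEM
#' catalogues with 1833 up / 1988 down calls), clusters whose sizes follow a
#' truncated geometric law with mean 688/143 (about 4.8 mature members, the
#' mean of public cluster catalogues), a 50% per-cancer association
#' probability, and strong but imperfect within-cluster co-direction
#' (`rho = 0.8`).
#'
#' @param nMirnas miRNA universe size (>= 2).
#' @param fracClustered fraction of the universe assigned to clusters.
#' @param meanClusterSize mean of the truncated geometric cluster size law.
#' @param minClusterSize minimum cluster size (>= 2).
#' @param nCancers number of cancer types.
#' @param pAssoc per-cancer probability that a miRNA is a DEM.
#' @param pUp probability an independent direction draw is UP.
#' @param rho co-direction probability: a clustered DEM copies its cluster's
#'   per-cancer consensus direction with probability `rho`, otherwise draws
#'   independently. `rho = 0` is the null (no co-dysregulation); `rho = 1`
#'   forces perfect homogeneity.
#' @param seed integer RNG seed for [simulateDEM()].
#' @return a [SimConfig-class].
#' @seealso [referenceConfig()], [simulateDEM()]
#' @export
simConfig <- function(nMirnas = 1588L, fracClustered = 688 / 1588,
                      meanClusterSize = 688 / 143, minClusterSize = 2L,
                      nCancers = 19L, pAssoc = 0.5, pUp = 0.48,
                      rho = 0.8, seed = 1L) {
    new("SimConfig", nMirnas = as.integer(nMirnas),
        fracClustered = fracClustered,
        meanClusterSize = meanClusterSize,
        minClusterSize = as.integer(minClusterSize),
        nCancers = as.integer(nCancers), pAssoc = pAssoc, pUp = pUp,
        rho = rho, seed = as.integer(seed))
}

#' Reference configuration mirroring the human pan-cancer setting
#'
#' Convenience wrapper returning [simConfig()]'s defaults: 1588 miRNAs with
#' 688 clustered, 19 cancer types, 48% up-direction balance.
#'
#' @param ... overrides passed on to [simConfig()].
#' @return a [SimConfig-class].
#' @export
referenceConfig <- function(...) simConfig(...)

# Truncated geometric cluster sizes summing exactly to `target`.
.drawClusterSizes <- function(target, minSize, meanSize) {
    p <- 1 / (meanSize - minSize + 1)
    sizes <- integer(0)
    total <- 0L
    while (total < target) {
        s <- minSize + stats::rgeom(1L, p)
        sizes <- c(sizes, s)
        total <- total + s
    }
    excess <- total - target
    if (excess > 0L) {
        n <- length(sizes)
        if (sizes[n] - excess >= minSize) {
            sizes[n] <- sizes[n] - excess
        } else if (n >= 2L) {
            # fold the remainder of the last cluster into its predecessor
            sizes[n - 1L] <- sizes[n - 1L] + sizes[n] - excess
            sizes <- sizes[-n]
        } else {
            sizes <- target
        }
    }
    sizes
}

#' Simulate a DEM matrix with planted cluster co-direction
#'
#' Generative model: the universe is split into clustered and non-clustered
#' miRNAs according to `fracClustered`, with cluster sizes drawn from a
#' truncated geometric law (minimum `minClusterSize`, mean
#' `meanClusterSize`). Independently per cancer type, each miRNA is a DEM
#' with probability `pAssoc`. Each (cluster, cancer) receives a consensus
#' direction (`UP` with probability `pUp`); an associated clustered miRNA
#' copies that consensus with probability `rho` and otherwise draws its
#' direction independently (`UP` with probability `pUp`), as do
#' non-clustered DEMs. A single seeded RNG stream drives the whole call and
#' the caller's RNG state is left untouched, so outputs are byte-reproducible
#' from `(config, seed)`.
#'
#' @param config a [SimConfig-class], see [simConfig()].
#' @param seed optional override of `config@seed`.
#' @return a list with elements `clusters` (a [ClusterSet-class]),
#'   `matrix` (a [DEMMatrix-class]) and `truth` (list: `membership`,
#'   `consensus` character matrix cluster x cancer, `planted` logical per
#'   cluster — `TRUE` when `rho > 0` plants co-direction — and the effective
#'   `rho` and `seed`).
#' @examples
#' sim <- simulateDEM(simConfig(nMirnas = 60, nCancers = 4, seed = 7))
#' sim$matrix
#' @export
simulateDEM <- function(config = simConfig(), seed = NULL) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (is.null(seed)) seed <- config@seed
    n <- config@nMirnas
    nc <- config@nCancers
    target <- round(config@fracClustered * n)
    if (target > 0 && target < config@minClusterSize)
        stop("infeasible cluster sizing: fracClustered * nMirnas = ",
             target, " < ", config@minClusterSize)
    .withSeed(seed, {
        sizes <- if (target > 0)
            .drawClusterSizes(target, config@minClusterSize,
                              config@meanClusterSize) else integer(0)
        nClustered <- sum(sizes)
        ids <- sprintf("syn-miR-%05d", seq_len(n))
        canc <- sprintf("cancer%02d", seq_len(nc))
        clusterOf <- rep(NA_integer_, n)
        if (length(sizes))
            clusterOf[seq_len(nClustered)] <-
                rep(seq_along(sizes), sizes)
        members <- if (length(sizes))
            split(ids[seq_len(nClustered)],
                  sprintf("CL%04d", clusterOf[seq_len(nClustered)]))
            else list()
        assoc <- matrix(stats::runif(n * nc) < config@pAssoc, n, nc)
        consensus <- matrix(
            ifelse(stats::runif(length(sizes) * nc) < config@pUp,
                   "UP", "DOWN"),
            nrow = length(sizes), ncol = nc,
            dimnames = list(names(members), canc))
        copy <- matrix(stats::runif(n * nc) < config@rho, n, nc)
        indep <- matrix(ifelse(stats::runif(n * nc) < config@pUp,
                               "UP", "DOWN"), n, nc)
        dir <- indep
        if (length(sizes)) {
            ci <- which(!is.na(clusterOf))
            dir[ci, ] <- ifelse(copy[ci, , drop = FALSE],
                                consensus[clusterOf[ci], , drop = FALSE],
                                indep[ci, , drop = FALSE])
        }
        dir[!assoc] <- NA_character_
        dimnames(dir) <- list(ids, canc)
        mat <- new("DEMMatrix", mat = dir,
                   provenance = sprintf("simulateDEM(seed=%d)", seed))
        clusters <- new("ClusterSet", members = as.list(members),
                        span = GenomicRanges::GRanges(),
                        metadata = list(source = "simulateDEM"))
        truth <- list(membership = as.list(members),
                      consensus = consensus,
                      planted = stats::setNames(
                          rep(config@rho > 0, length(members)),
                          names(members)),
                      rho = config@rho, seed = seed)
        list(clusters = clusters, matrix = mat, truth = truth)
    })
}

#' Write a simulated bundle to disk
#'
#' Emits the same TSV dialects the readers consume: `dem_calls.tsv` (one
#' synthetic experiment per cancer), `dem_matrix.tsv`, `clusters.tsv`, and
#' the ground truth as `truth.json`.
#'
#' @param sim result of [simulateDEM()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- directionMatrix(sim$matrix)
    idx <- which(!is.na(m), arr.ind = TRUE)
    calls <- DEMCallSet(data.frame(
        mature_id = rownames(m)[idx[, 1L]],
        cancer = colnames(m)[idx[, 2L]],
        experiment_id = paste0("SIM_", colnames(m)[idx[, 2L]]),
        direction = m[idx]))
    files <- c(dem_calls = file.path(dir, "dem_calls.tsv"),
               dem_matrix = file.path(dir, "dem_matrix.tsv"),
               clusters = file.path(dir, "clusters.tsv"),
               truth = file.path(dir, "truth.json"))
    writeDEMTable(calls, files[["dem_calls"]])
    writeDEMMatrix(sim$matrix, files[["dem_matrix"]])
    writeClusterTable(sim$clusters, files[["clusters"]])
    truth <- sim$truth
    truth$consensus <- as.data.frame(truth$consensus)
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(files)
}
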