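#' @include AllGenerics.R
NULL

#' Run the full cluster co-dysregulation analysis
#'
#' Ties the stages together the way the pan-cancer analysis is meant to be
#' run: consolidate experiment-level calls into a per-cancer matrix, filter
#' clusters by annotation coverage, score cluster homogeneity against the
#' marginal-preserving permutation null, compute the per-cancer LOD
#' enrichment profile, and derive vote-counting consistency scores. All
#' results are written as TSV/JSON into `outDir` together with a run
#' manifest (`manifest.json`) listing an MD5 digest for every emitted file,
#' the seed, the effective configuration and the package version. Given the
#' same inputs and seed the result files are byte-identical across runs.
#'
#' @param dem a [DEMCallSet-class], or the path of a DEM call TSV for
#'   [readDEMTable()].
#' @param clusters a [ClusterSet-class], or the path of a cluster
#'   membership TSV for [readClusterTable()].
#' @param outDir output directory (created if needed).
#' @param policy a [homogeneityPolicy()] (controls the permutation count
#'   through `nPerm`).
#' @param minAnnotatedFraction cluster retention threshold for
#'   [filterClusters()].
#' @param xAll,yAll universe counts for [enrichmentProfile()]; `NULL`
#'   derives them from the data.
#' @param alpha significance level for the summary count of significant
#'   clusters (raw p, as the analysis thresholds raw P < 0.05).
#' @param seed integer seed driving every stochastic stage.
#' @return invisibly, a list with elements `matrix`, `clusters`,
#'   `homogeneity`, `enrichment`, `consistency`, `summary` and
#'   `manifest`.
#' @export
runFullAnalysis <- function(dem, clusters, outDir,
                            policy = homogeneityPolicy(),
                            minAnnotatedFraction = 0.5,
                            xAll = NULL, yAll = NULL,
                            alpha = 0.05, seed = 1L) {
    t0 <- Sys.time()
    if (is.character(dem)) {
        if (!file.exists(dem)) stop("DEM table not found: ", dem)
        dem <- readDEMTable(dem)
    }
    if (is.character(clusters)) {
        if (!file.exists(clusters))
            stop("cluster table not found: ", clusters)
        clusters <- readClusterTable(clusters)
    }
    stopifnot(is(dem, "DEMCallSet"), is(clusters, "ClusterSet"))
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

    mat <- consolidate(dem)
    kept <- filterClusters(mat, clusters, minAnnotatedFraction)
    homog <- homogeneityTest(mat, kept, policy, seed = seed)
    enr <- enrichmentPermutation(mat, kept, nPerm = policy@nPerm,
                                 seed = seed, pseudocount = 0.5)
    cons <- consistencyScores(dem)

    emd <- S4Vectors::metadata(enr)
    summary <- list(
        n_clusters_input = length(clusterIds(clusters)),
        n_clusters_retained = length(clusterIds(kept)),
        n_clusters_scored = nrow(homog),
        mean_homogeneous_fraction = mean(homog$homogeneous_fraction),
        n_significant = sum(homog$p_value < alpha),
        frac_significant = mean(homog$p_value < alpha),
        alpha = alpha,
        mean_lod = emd$mean_lod,
        mean_fold = emd$mean_fold,
        fold_of_mean_lod = emd$fold_of_mean_lod,
        n_cancers_positive = emd$n_cancers_positive,
        n_cancers = length(cancers(mat)),
        global_p_label = emd$global_p_label)

    files <- c(dem_matrix = file.path(outDir, "dem_matrix.tsv"),
               clusters_retained = file.path(outDir,
                                             "clusters_retained.tsv"),
               homogeneity = file.path(outDir, "homogeneity.tsv"),
               enrichment = file.path(outDir, "enrichment.tsv"),
               consistency = file.path(outDir, "consistency.tsv"),
               summary = file.path(outDir, "summary.json"))
    writeDEMMatrix(mat, files[["dem_matrix"]])
    writeClusterTable(kept, files[["clusters_retained"]])
    .writeTSV(as.data.frame(homog), files[["homogeneity"]])
    .writeTSV(as.data.frame(enr), files[["enrichment"]])
    .writeTSV(as.data.frame(cons), files[["consistency"]])
    jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)

    manifest <- list(
        tool = "DEMcluster::runFullAnalysis",
        version = as.character(utils::packageVersion("DEMcluster")),
        seed = seed,
        config = list(
            n_perm = policy@nPerm,
            exceedance = policy@exceedance,
            tie_is_homogeneous = policy@tieIsHomogeneous,
            min_members_per_cancer = policy@minMembersPerCancer,
            min_annotated_fraction = minAnnotatedFraction,
            x_all = emd$x_all, y_all = emd$y_all,
            alpha = alpha),
        started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        outputs = lapply(files, function(f)
            list(path = basename(f),
                 md5 = unname(tools::md5sum(f)))))
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)

    invisible(list(matrix = mat, clusters = kept, homogeneity = homog,
                   enrichment = enr, consistency = cons,
                   summary = summary, manifest = manifest))
}
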