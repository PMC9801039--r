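#' @include AllGenerics.R
NULL

#' Conventions for the cluster homogeneity statistic
#'
#' A cluster is scored per cancer type on its direction-called members: with
#' `n_up` members called UP and `n_down` called DOWN, the cancer is
#' *eligible* when `n_up + n_down >= minMembersPerCancer`, and *homogeneous*
#' when at least half of the called members share one direction. Because
#' only two directions exist, the majority always reaches half, so under the
#' literal rule every eligible cancer is homogeneous and only exact ties can
#' break homogeneity: `tieIsHomogeneous = FALSE` selects the non-degenerate
#' strict-majority variant. The `exceedance` rule fixes how the permutation
#' p-value counts null fractions against the observed one: `"strict"` counts
#' `>` (so a perfect observed fraction yields p = 0), `"weak"` counts `>=`,
#' and `"add_one"` returns `(#\{>=\} + 1) / (nPerm + 1)`, which is never 0
#' and is a valid p-value under exchangeability.
#'
#' @param minMembersPerCancer minimum called members per cancer (default 2).
#' @param tieIsHomogeneous does an exact UP/DOWN tie count as homogeneous?
#'   Default `TRUE` (the literal "at least half" reading).
#' @param exceedance `"strict"` (default), `"weak"`, or `"add_one"`.
#' @param nPerm number of permutation replicates (default 10000).
#' @return a [HomogeneityPolicy-class].
#' @export
homogeneityPolicy <- function(minMembersPerCancer = 2L,
                              tieIsHomogeneous = TRUE,
                              exceedance = c("strict", "weak", "add_one"),
                              nPerm = 10000L) {
    new("HomogeneityPolicy",
        minMembersPerCancer = as.integer(minMembersPerCancer),
        tieIsHomogeneous = tieIsHomogeneous,
        exceedance = match.arg(exceedance), nPerm = as.integer(nPerm))
}

#' Discard clusters with insufficient cancer annotation
#'
#' Retains clusters in which at least `minAnnotatedFraction` of the members
#' are associated with (called a DEM in) at least one cancer type; the rest
#' — including clusters with no associated member at all — are discarded.
#' Members missing from the matrix count as never associated.
#'
#' @param x a [DEMMatrix-class].
#' @param clusters a [ClusterSet-class].
#' @param minAnnotatedFraction retention threshold (default 0.5, i.e. "at
#'   least half the members associated with some cancer").
#' @return the filtered [ClusterSet-class].
#' @export
filterClusters <- function(x, clusters, minAnnotatedFraction = 0.5) {
    stopifnot(is(x, "DEMMatrix"), is(clusters, "ClusterSet"))
    m <- directionMatrix(x)
    assocAny <- rownames(m)[rowSums(!is.na(m)) > 0L]
    mem <- clusterMembers(clusters)
    frac <- vapply(mem, function(ids) mean(ids %in% assocAny), numeric(1))
    keep <- frac >= minAnnotatedFraction
    span <- clusterSpans(clusters)
    span <- span[names(span) %in% names(mem)[keep]]
    md <- clusters@metadata
    md$filtered_out <- names(mem)[!keep]
    new("ClusterSet", members = mem[keep], span = span, metadata = md)
}

# Internal geometry shared by the observed and permuted statistics.
# Returns per-cancer association indices plus, for the cluster members,
# their positions inside each cancer's associated set.
.homogSetup <- function(mat, members) {
    u <- !is.na(mat) & (mat == "UP")
    cal <- !is.na(mat)
    K <- length(members)
    rows <- lapply(members, function(ids)
        stats::na.omit(match(ids, rownames(mat))))
    g <- rep(seq_len(K), lengths(rows))
    rowsV <- unlist(rows, use.names = FALSE)
    perCancer <- lapply(seq_len(ncol(mat)), function(j) {
        A <- which(cal[, j])
        sel <- cal[rowsV, j]
        list(upA = u[A, j], pos = match(rowsV[sel], A), grp = g[sel],
             nAssoc = length(A))
    })
    nCall <- vapply(perCancer, function(pc) tabulate(pc$grp, K),
                    integer(K))
    nCall <- matrix(nCall, nrow = K)
    list(perCancer = perCancer, nCall = nCall, K = K)
}

.homogFractions <- function(setup, policy, permute = FALSE) {
    K <- setup$K
    nUp <- vapply(setup$perCancer, function(pc) {
        lab <- if (permute) pc$upA[sample.int(pc$nAssoc)] else pc$upA
        tabulate(pc$grp[lab[pc$pos]], K)
    }, integer(K))
    nUp <- matrix(nUp, nrow = K)
    elig <- setup$nCall >= policy@minMembersPerCancer
    tie <- (2L * nUp) == setup$nCall
    homog <- elig & (policy@tieIsHomogeneous | !tie)
    nElig <- rowSums(elig)
    frac <- ifelse(nElig > 0L, rowSums(homog) / pmax(nElig, 1L), NA_real_)
    list(nUp = nUp, elig = elig, tie = tie, homog = homog, frac = frac,
         nElig = nElig)
}

#' Per-cluster, per-cancer direction states
#'
#' Tallies UP/DOWN calls of each cluster's members in each cancer and
#' applies the homogeneity rule of `policy`. `direction` is the majority
#' direction, `"TIE"` on an exact split, and `NA` for ineligible cancers
#' (fewer called members than `minMembersPerCancer`).
#'
#' @param x a [DEMMatrix-class].
#' @param clusters a [ClusterSet-class] (typically pre-filtered with
#'   [filterClusters()]).
#' @param policy a [homogeneityPolicy()].
#' @return a `DataFrame` with columns `cluster_id`, `cancer`, `n_up`,
#'   `n_down`, `eligible`, `homogeneous`, `direction`.
#' @export
clusterCancerStates <- function(x, clusters, policy = homogeneityPolicy()) {
    stopifnot(is(x, "DEMMatrix"), is(clusters, "ClusterSet"))
    mat <- directionMatrix(x)
    mem <- clusterMembers(clusters)
    setup <- .homogSetup(mat, mem)
    st <- .homogFractions(setup, policy)
    nDown <- setup$nCall - st$nUp
    dir <- matrix(NA_character_, setup$K, ncol(mat))
    dir[st$nUp > nDown] <- "UP"
    dir[st$nUp < nDown] <- "DOWN"
    dir[st$tie & setup$nCall > 0L] <- "TIE"
    dir[!st$elig] <- NA_character_
    DataFrame(cluster_id = rep(names(mem), ncol(mat)),
              cancer = rep(colnames(mat), each = setup$K),
              n_up = as.vector(st$nUp),
              n_down = as.vector(nDown),
              eligible = as.vector(st$elig),
              homogeneous = as.vector(st$homog),
              direction = as.vector(dir))
}

#' Homogeneous fraction of a single cluster
#'
#' The fraction of eligible cancer types in which the cluster's called
#' members are homogeneous under `policy`.
#'
#' @param x a [DEMMatrix-class].
#' @param members character vector of the cluster's member miRNA ids.
#' @param policy a [homogeneityPolicy()].
#' @return a number in `[0, 1]`, or `NA` (with a warning) when no cancer is
#'   eligible.
#' @export
homogeneousFraction <- function(x, members,
                                policy = homogeneityPolicy()) {
    setup <- .homogSetup(directionMatrix(x), list(cluster = members))
    st <- .homogFractions(setup, policy)
    if (st$nElig[1L] == 0L) {
        warning("no eligible cancer type for this cluster; ",
                "fraction undefined")
        return(NA_real_)
    }
    st$frac[1L]
}

#' Permute direction labels within each cancer type
#'
#' The permutation null of [homogeneityTest()], exposed for inspection:
#' within every cancer, the multiset of UP/DOWN labels over that cancer's
#' associated miRNAs is uniformly permuted. Which miRNAs are associated
#' with which cancer is left untouched, so per-cancer UP and DOWN totals
#' are preserved exactly.
#'
#' @param x a [DEMMatrix-class].
#' @param seed optional seed for a private RNG stream.
#' @return a [DEMMatrix-class] with permuted labels.
#' @export
permuteDirections <- function(x, seed = NULL) {
    stopifnot(is(x, "DEMMatrix"))
    .withSeed(seed, {
        m <- directionMatrix(x)
        for (j in seq_len(ncol(m))) {
            A <- which(!is.na(m[, j]))
            if (length(A) > 1L)
                m[A, j] <- m[A[sample.int(length(A))], j]
        }
        new("DEMMatrix", mat = m,
            provenance = paste0(x@provenance, "+permuted"))
    })
}

#' Permutation test of cluster co-dysregulation
#'
#' For every cluster the observed homogeneous fraction (see
#' [homogeneousFraction()]) is compared against a marginal-preserving
#' permutation null: in each replicate and each cancer type, the UP/DOWN
#' labels of that cancer's associated miRNAs are uniformly permuted among
#' those miRNAs — the association pattern and the per-cancer direction
#' totals stay fixed — and all cluster fractions are recomputed. The
#' p-value counts null fractions against the observed one under the
#' policy's exceedance rule; Benjamini-Hochberg q-values are reported
#' alongside. Cancers ineligible for a cluster are excluded from both the
#' observed and every permuted fraction (the eligibility set is identical
#' across replicates since association is fixed); clusters with no eligible
#' cancer are skipped with a warning.
#'
#' @param x a [DEMMatrix-class]. All associated miRNAs in the matrix form
#'   the per-cancer permutation pool; restrict the matrix first if a
#'   narrower universe is wanted.
#' @param clusters a [ClusterSet-class], typically [filterClusters()]
#'   output.
#' @param policy a [homogeneityPolicy()]; `policy@nPerm` sets the replicate
#'   count.
#' @param seed integer seed for the single RNG stream of the test.
#' @return a `DataFrame` with one row per scored cluster: `cluster_id`,
#'   `n_members`, `eligible_cancers`, `homogeneous_fraction`, `p_strict`,
#'   `p_weak`, `p_add_one`, `p_value` (the policy's rule), `q_value`, and
#'   `directions` (per-cancer majority directions, comma-separated).
#'   `metadata()` carries the policy, seed and cancer names.
#' @examples
#' sim <- simulateDEM(simConfig(nMirnas = 80, nCancers = 5, seed = 3))
#' res <- homogeneityTest(sim$matrix, sim$clusters,
#'                        homogeneityPolicy(nPerm = 200), seed = 42)
#' head(res)
#' @export
homogeneityTest <- function(x, clusters, policy = homogeneityPolicy(),
                            seed = 1L) {
    stopifnot(is(x, "DEMMatrix"), is(clusters, "ClusterSet"),
              is(policy, "HomogeneityPolicy"))
    validObject(policy)
    mat <- directionMatrix(x)
    mem <- clusterMembers(clusters)
    setup <- .homogSetup(mat, mem)
    obs <- .homogFractions(setup, policy)
    scored <- which(obs$nElig > 0L)
    if (length(scored) < length(mem))
        warning(length(mem) - length(scored),
                " cluster(s) with no eligible cancer type skipped")
    eps <- 1e-12
    cGT <- cGE <- integer(setup$K)
    .withSeed(seed, {
        for (r in seq_len(policy@nPerm)) {
            fr <- .homogFractions(setup, policy, permute = TRUE)$frac
            cGT <- cGT + as.integer(fr > obs$frac + eps)
            cGE <- cGE + as.integer(fr >= obs$frac - eps)
        }
    })
    pStrict <- cGT / policy@nPerm
    pWeak <- cGE / policy@nPerm
    pAdd <- (cGE + 1) / (policy@nPerm + 1)
    pSel <- switch(policy@exceedance, strict = pStrict, weak = pWeak,
                   add_one = pAdd)
    states <- clusterCancerStates(x, clusters, policy)
    dirStr <- vapply(names(mem), function(id) {
        s <- states[states$cluster_id == id & states$eligible, ]
        paste(paste0(s$cancer, ":", s$direction), collapse = ",")
    }, character(1))
    res <- DataFrame(
        cluster_id = names(mem)[scored],
        n_members = lengths(mem)[scored],
        eligible_cancers = obs$nElig[scored],
        homogeneous_fraction = obs$frac[scored],
        p_strict = pStrict[scored],
        p_weak = pWeak[scored],
        p_add_one = pAdd[scored],
        p_value = pSel[scored],
        directions = dirStr[scored])
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res <- res[, c("cluster_id", "n_members", "eligible_cancers",
                   "homogeneous_fraction", "p_strict", "p_weak",
                   "p_add_one", "p_value", "q_value", "directions")]
    S4Vectors::metadata(res) <- list(policy = policy, seed = seed,
                                     cancers = colnames(mat),
                                     nPerm = policy@nPerm)
    res
}
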