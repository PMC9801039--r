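threeClusterMatrix <- function() {
    # 4-member clusters with 1, 2 and 0 ever-associated members
    m <- matrix(NA_character_, 12, 2,
                dimnames = list(sprintf("m%02d", 1:12), c("X", "Y")))
    m["m01", "X"] <- "UP"                     # cluster A: 1/4 associated
    m["m05", "X"] <- "UP"; m["m06", "Y"] <- "DOWN"  # cluster B: 2/4
    DEMMatrix(m)
}

test_that("clusters with under-annotated membership are discarded", {
    cl <- ClusterSet(list(A = sprintf("m%02d", 1:4),
                          B = sprintf("m%02d", 5:8),
                          C = sprintf("m%02d", 9:12)))
    kept <- filterClusters(threeClusterMatrix(), cl)
    expect_identical(clusterIds(kept), "B")   # 2/4 boundary retained
    expect_setequal(kept@metadata$filtered_out, c("A", "C"))
    expect_identical(clusterIds(filterClusters(threeClusterMatrix(), cl,
                                               minAnnotatedFraction = 0.25)),
                     c("A", "B"))
})

test_that("per-cancer states count directions and apply the eligibility rule", {
    m <- oneCancerMatrix(c("UP", "UP", "DOWN", "UP", NA))
    cl <- ClusterSet(list(K = c("m01", "m02", "m03")))
    st <- clusterCancerStates(m, cl)
    expect_identical(st$n_up, 2L)
    expect_identical(st$n_down, 1L)
    expect_true(st$homogeneous)               # 2/3 >= half
    expect_identical(st$direction, "UP")

    tied <- clusterCancerStates(oneCancerMatrix(c("UP", "DOWN")),
                                ClusterSet(list(K = c("m01", "m02"))))
    expect_identical(tied$direction, "TIE")
    expect_true(tied$homogeneous)             # tie homogeneous by default

    single <- clusterCancerStates(oneCancerMatrix(c("UP", NA, NA)),
                                  ClusterSet(list(K = c("m01", "m02"))))
    expect_false(single$eligible)             # 1 called < minMembers 2
    expect_true(is.na(single$direction))
})

test_that("homogeneous fractions average over eligible cancers only", {
    # 12 cancers, homogeneous in 11: fraction 11/12
    m <- matrix(NA_character_, 4, 12,
                dimnames = list(c("a", "b", "c", "d"),
                                sprintf("C%02d", 1:12)))
    m["a", ] <- "UP"
    m["b", ] <- c(rep("UP", 11), "DOWN")
    m["c", 12] <- "DOWN"; m["d", 12] <- "UP"  # C12: 2 up vs 2 down tie
    x <- DEMMatrix(m)
    pol <- homogeneityPolicy(tieIsHomogeneous = FALSE)
    expect_equal(homogeneousFraction(x, c("a", "b", "c", "d"), pol),
                 11 / 12)
    expect_identical(homogeneousFraction(x, c("a", "b")), 1)
    allTied <- DEMMatrix(matrix(c("UP", "DOWN"), 2, 5,
        byrow = FALSE, dimnames = list(c("a", "b"), sprintf("C%d", 1:5))))
    expect_identical(homogeneousFraction(allTied, c("a", "b"), pol), 0)
    expect_warning(
        expect_true(is.na(homogeneousFraction(x, c("zz", "ww")))),
        "no eligible")
})

test_that("label permutation preserves per-cancer marginals exactly", {
    sim <- simulateDEM(simConfig(nMirnas = 300, nCancers = 8, seed = 21))
    m <- directionMatrix(sim$matrix)
    obsUp <- colSums(m == "UP", na.rm = TRUE)
    obsDown <- colSums(m == "DOWN", na.rm = TRUE)
    for (r in 1:50) {
        p <- directionMatrix(permuteDirections(sim$matrix, seed = r))
        expect_identical(colSums(p == "UP", na.rm = TRUE), obsUp)
        expect_identical(colSums(p == "DOWN", na.rm = TRUE), obsDown)
        expect_identical(is.na(p), is.na(m))  # association fixed
    }
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration", {
    # one cancer, 6 associated miRNAs (3 UP / 3 DOWN), one 2-member cluster
    up <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
    m <- oneCancerMatrix(ifelse(up, "UP", "DOWN"))
    cl <- ClusterSet(list(K = c("m01", "m02")))
    pol <- homogeneityPolicy(tieIsHomogeneous = FALSE, nPerm = 4000L)
    res <- homogeneityTest(m, cl, pol, seed = 5)
    ex <- exactPermP(up, memberPos = 1:2)
    se <- sqrt(ex$pGT * (1 - ex$pGT) / pol@nPerm)
    expect_lt(abs(res$p_strict - ex$pGT), max(3 * se, 1e-9))
    seW <- sqrt(ex$pGE * (1 - ex$pGE) / pol@nPerm)
    expect_lt(abs(res$p_weak - ex$pGE), max(3 * seW, 1e-9))
})

test_that("exceedance rules are ordered and bounded", {
    sim <- simulateDEM(simConfig(nMirnas = 200, nCancers = 6, seed = 31))
    pol <- homogeneityPolicy(tieIsHomogeneous = FALSE, nPerm = 300L)
    res <- homogeneityTest(sim$matrix, sim$clusters, pol, seed = 7)
    expect_true(all(res$p_strict <= res$p_weak))
    expect_true(all(res$p_add_one > 0 & res$p_add_one <= 1))
    expect_true(all(res$p_value == res$p_strict))  # default policy rule
    expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("a perfect observed fraction has strict-exceedance p of zero", {
    m <- oneCancerMatrix(c("UP", "UP", "DOWN", "DOWN", "UP"))
    cl <- ClusterSet(list(K = c("m01", "m02")))   # observed: both UP
    pol <- homogeneityPolicy(tieIsHomogeneous = FALSE, nPerm = 500L)
    res <- homogeneityTest(m, cl, pol, seed = 2)
    expect_identical(res$homogeneous_fraction, 1)
    expect_identical(res$p_strict, 0)
})

test_that("an all-UP cancer is invariant under permutation", {
    m <- matrix(c("UP", "UP", "UP", "UP",
                  "UP", "DOWN", "UP", "DOWN"), ncol = 2,
                dimnames = list(sprintf("m%02d", 1:4), c("A", "B")))
    x <- DEMMatrix(m)
    for (r in 1:10)
        expect_identical(directionMatrix(
            permuteDirections(x, seed = r))[, "A"], m[, "A"])
})

test_that("null p-values are stochastically no smaller than uniform", {
    sim <- simulateDEM(simConfig(nMirnas = 1200, rho = 0, nCancers = 19,
                                 seed = 41))
    kept <- filterClusters(sim$matrix, sim$clusters)
    pol <- homogeneityPolicy(tieIsHomogeneous = FALSE, nPerm = 300L,
                             exceedance = "add_one")
    res <- homogeneityTest(sim$matrix, kept, pol, seed = 42)
    n <- nrow(res)
    for (a in c(0.05, 0.1, 0.25, 0.5)) {
        bound <- a + 2.576 * sqrt(a * (1 - a) / n)
        expect_lt(mean(res$p_add_one <= a), bound)
    }
})

test_that("planted co-direction is detected (power at rho = 0.95)", {
    sim <- simulateDEM(simConfig(nMirnas = 700, rho = 0.95,
                                 minClusterSize = 3L, pAssoc = 0.6,
                                 seed = 51))
    kept <- filterClusters(sim$matrix, sim$clusters)
    pol <- homogeneityPolicy(tieIsHomogeneous = FALSE, nPerm = 400L)
    res <- homogeneityTest(sim$matrix, kept, pol, seed = 52)
    expect_lt(median(res$p_add_one), 0.05)
})

test_that("the permutation test is deterministic given a seed", {
    sim <- simulateDEM(simConfig(nMirnas = 150, nCancers = 5, seed = 61))
    pol <- homogeneityPolicy(nPerm = 100L, tieIsHomogeneous = FALSE)
    a <- homogeneityTest(sim$matrix, sim$clusters, pol, seed = 9)
    b <- homogeneityTest(sim$matrix, sim$clusters, pol, seed = 9)
    expect_identical(as.data.frame(a), as.data.frame(b))
    c_ <- homogeneityTest(sim$matrix, sim$clusters, pol, seed = 10)
    expect_false(identical(a$p_weak, c_$p_weak))
})
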