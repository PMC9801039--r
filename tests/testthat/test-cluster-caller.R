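grFromTable <- function(chrom, start, end, strand = "+", ids = NULL) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start, end = end), strand = strand)
    names(gr) <- if (is.null(ids)) sprintf("pre%02d", seq_along(gr)) else ids
    gr
}

test_that("precursors chain by gap, ignoring orientation", {
    near <- grFromTable("chr17", c(1000, 6100), c(1100, 6200),
                        strand = c("+", "-"))
    cl <- callClusters(near, maxGap = 10000)          # 5000 bp gap
    expect_length(clusterIds(cl), 1L)
    expect_setequal(clusterMembers(cl)[[1]], names(near))

    far <- grFromTable("chr17", c(1000, 51100), c(1100, 51200))
    cl2 <- callClusters(far, maxGap = 10000)          # 50000 bp gap
    expect_length(clusterIds(cl2), 0L)
    expect_setequal(cl2@metadata$singletons, names(far))

    opp <- grFromTable("chr5", c(100, 1200), c(180, 1280),
                       strand = c("+", "-"))          # 1019 bp gap
    expect_length(clusterIds(callClusters(opp, maxGap = 10000)), 1L)
})

test_that("interruptions break chains only when wholly between precursors", {
    gr <- grFromTable("chr1", c(1000, 4000, 7000), c(1100, 4100, 7100))
    gene <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(2000, 2500))
    cl <- callClusters(gr, maxGap = 10000, interruptions = gene)
    expect_identical(canonicalClusters(clusterMembers(cl)),
                     list(c("pre02", "pre03")))
    # overlapping the precursor, not between: no break
    touching <- GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(1050, 2500))
    cl2 <- callClusters(gr, maxGap = 10000, interruptions = touching)
    expect_length(clusterIds(cl2), 1L)
    expect_length(clusterMembers(cl2)[[1]], 3L)
    # other chromosome: ignored
    other <- GenomicRanges::GRanges("chr2", IRanges::IRanges(2000, 2500))
    expect_length(clusterMembers(
        callClusters(gr, maxGap = 10000, interruptions = other))[[1]], 3L)
})

test_that("duplicate precursor ids are rejected and order does not matter", {
    gr <- grFromTable("chr1", c(100, 300), c(200, 400),
                      ids = c("p1", "p1"))
    expect_error(callClusters(gr), "duplicated precursor")

    gr2 <- randomPrecursors(60, seed = 99)
    a <- callClusters(gr2, maxGap = 4000)
    b <- callClusters(gr2[sample.int(length(gr2))], maxGap = 4000)
    expect_identical(canonicalClusters(clusterMembers(a)),
                     canonicalClusters(clusterMembers(b)))
})

test_that("cluster spans cover their members", {
    gr <- grFromTable("chr3", c(500, 2000, 3500), c(600, 2100, 3600))
    cl <- callClusters(gr, maxGap = 2000)
    sp <- clusterSpans(cl)
    expect_identical(GenomicRanges::start(sp)[[1]], 500L)
    expect_identical(GenomicRanges::end(sp)[[1]], 3600L)
})

test_that("greedy chaining matches the brute-force transitive closure", {
    for (seed in 1:20) {
        gr <- randomPrecursors(sample(5:60, 1), seed = seed)
        maxGap <- sample(c(0, 500, 5000, 20000), 1)
        got <- canonicalClusters(
            clusterMembers(callClusters(gr, maxGap = maxGap)))
        expect_identical(got, bruteClusters(gr, maxGap),
                         info = paste("seed", seed, "maxGap", maxGap))
    }
    # with interruptions, on non-overlapping instances
    for (seed in 21:26) {
        gr <- randomPrecursors(30, seed = seed, overlap = FALSE)
        intr <- randomPrecursors(8, seed = seed + 100, overlap = FALSE)
        names(intr) <- NULL
        got <- canonicalClusters(clusterMembers(
            callClusters(gr, maxGap = 15000, interruptions = intr)))
        expect_identical(got, bruteClusters(gr, 15000, intr),
                         info = paste("interrupted seed", seed))
    }
})

test_that("mature expansion unions arms and applies the size rule", {
    ann <- readMirnaGFF(system.file("extdata", "synthetic_mirna.gff3",
                                    package = "DEMcluster"))
    expect_length(ann$precursors, 4L)
    expect_length(ann$matures, 6L)
    expect_identical(unname(ann$matures$precursor_id[1]), "syn-mir-1")

    cl <- callClusters(ann$precursors, maxGap = 10000)
    expect_identical(canonicalClusters(clusterMembers(cl)),
                     list(c("syn-mir-1", "syn-mir-2")))
    mature <- mapMature(cl, ann$matures)
    expect_setequal(clusterMembers(mature)[[1]],
                    c("syn-miR-1-5p", "syn-miR-1-3p", "syn-miR-2-5p"))

    # a 2-precursor cluster collapsing to one mature id is dropped
    md <- data.frame(mature_id = c("x-5p", "x-5p"),
                     precursor_id = c("syn-mir-1", "syn-mir-2"))
    expect_message(dropped <- mapMature(cl, md), "dropping")
    expect_length(clusterIds(dropped), 0L)
})

test_that("cluster membership tables obey size and uniqueness rules", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("cluster_id\tmirna_id", "C1\ta", "C1\tb", "C2\tc"), path)
    expect_warning(cl <- readClusterTable(path), "C2")
    expect_identical(clusterIds(cl), "C1")
    expect_setequal(clusterMembers(cl)$C1, c("a", "b"))

    dup <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("cluster_id\tmirna_id", "C1\ta", "C1\tb",
                 "C2\ta", "C2\tz"), dup)
    expect_error(readClusterTable(dup), "more than one cluster")

    empty <- withr::local_tempfile(fileext = ".tsv")
    writeLines("cluster_id\tmirna_id", empty)
    expect_length(clusterIds(readClusterTable(empty)), 0L)

    out <- withr::local_tempfile(fileext = ".tsv")
    writeClusterTable(cl, out)
    expect_identical(clusterMembers(readClusterTable(out)),
                     clusterMembers(cl))
})

test_that("cluster spans export as 0-based half-open BED", {
    gr <- grFromTable("chr3", c(500, 2000), c(600, 2100))
    cl <- callClusters(gr, maxGap = 5000)
    bed <- withr::local_tempfile(fileext = ".bed")
    writeClusterBED(cl, bed)
    fields <- strsplit(readLines(bed)[1], "\t")[[1]]
    expect_identical(fields[1:3], c("chr3", "499", "2100"))
})
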