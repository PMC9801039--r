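# Independent oracles and small builders used across the suite.

# O(n^2) transitive-closure cluster oracle: edges connect precursors on the
# same chromosome whose interval gap is <= maxGap and with no interruption
# interval lying wholly between them; clusters = connected components of
# size >= 2. Returns a canonical form comparable across implementations.
bruteClusters <- function(gr, maxGap, interruptions = NULL) {
    n <- length(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j || chrom[i] != chrom[j]) next
        lo <- min(e[i], e[j]); hi <- max(s[i], s[j])
        gap <- hi - lo - 1L
        if (gap > maxGap) next
        broken <- FALSE
        if (!is.null(interruptions) && length(interruptions)) {
            ic <- as.character(GenomicRanges::seqnames(interruptions))
            broken <- any(ic == chrom[i] &
                          GenomicRanges::start(interruptions) > lo &
                          GenomicRanges::end(interruptions) < hi)
        }
        adj[i, j] <- !broken
    }
    adj <- adj | t(adj)
    comp <- rep(NA_integer_, n)
    cur <- 0L
    for (v in seq_len(n)) {
        if (!is.na(comp[v])) next
        cur <- cur + 1L
        stack <- v
        while (length(stack)) {
            u <- stack[[1L]]; stack <- stack[-1L]
            if (!is.na(comp[u])) next
            comp[u] <- cur
            stack <- c(stack, which(adj[u, ] & is.na(comp)))
        }
    }
    groups <- split(names(gr), comp)
    groups <- groups[lengths(groups) >= 2L]
    canonicalClusters(groups)
}

# order-independent canonical form of a membership list
canonicalClusters <- function(members) {
    out <- lapply(unname(members), sort)
    out[order(vapply(out, `[`, character(1), 1L))]
}

# Exhaustive enumeration oracle for the single-cancer permutation null:
# all C(n, n_up) placements of the UP labels over the n associated miRNAs
# are equally likely. Returns exact strict / weak exceedance p-values for
# one cluster occupying `memberPos` of the associated set.
exactPermP <- function(up, memberPos, tieHomog = FALSE, minMembers = 2L) {
    n <- length(up)
    nu <- sum(up)
    homogOf <- function(lab) {
        nc <- length(memberPos)
        if (nc < minMembers) return(NA_real_)
        nUp <- sum(lab[memberPos])
        tie <- (2L * nUp) == nc
        as.numeric(tieHomog || !tie)
    }
    obs <- homogOf(up)
    sets <- utils::combn(n, nu)
    fr <- apply(sets, 2L, function(ix) {
        lab <- rep(FALSE, n); lab[ix] <- TRUE
        homogOf(lab)
    })
    list(obs = obs, pGT = mean(fr > obs + 1e-12),
         pGE = mean(fr >= obs - 1e-12))
}

# DEMMatrix with one cancer from an explicit direction vector
oneCancerMatrix <- function(directions, cancer = "C1") {
    m <- matrix(directions, ncol = 1,
                dimnames = list(sprintf("m%02d", seq_along(directions)),
                                cancer))
    DEMMatrix(m)
}

# random precursor GRanges on a couple of chromosomes
randomPrecursors <- function(n, seed, overlap = TRUE) {
    withr::with_seed(seed, {
        chrom <- sample(c("chr1", "chr2", "chr9"), n, replace = TRUE)
        if (overlap) {
            s <- sample.int(2e5, n, replace = TRUE)
            w <- sample(60:12000, n, replace = TRUE)
        } else {
            s <- sort(sample.int(5e5, n))
            w <- sample(60:120, n, replace = TRUE)
        }
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = s, width = w),
            strand = sample(c("+", "-"), n, replace = TRUE))
        names(gr) <- sprintf("pre%03d", seq_len(n))
        gr
    })
}

simpleCallSet <- function(mirna, cancer, experiment, direction) {
    DEMCallSet(data.frame(mature_id = mirna, cancer = cancer,
                          experiment_id = experiment,
                          direction = direction))
}
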