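## Brute-force oracles and shared fixtures, independent of the package's
## overlap machinery (plain arithmetic on start/end vectors throughout).

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

## any-overlap (>= 1 shared base, 1-based closed coordinates) of each
## query interval against a whole subject set, by exhaustive comparison
bruteOverlapAny <- function(query, subject) {
    qc <- as.character(seqnames(query)); qs <- start(query); qe <- end(query)
    sc <- as.character(seqnames(subject)); ss <- start(subject)
    se <- end(subject)
    vapply(seq_along(query), function(i)
        any(sc == qc[i] & ss <= qe[i] & se >= qs[i]), logical(1))
}

## exhaustive per-pair overlap count for one query against a subject set
bruteOverlapCount <- function(query, subject) {
    qc <- as.character(seqnames(query)); qs <- start(query); qe <- end(query)
    sc <- as.character(seqnames(subject)); ss <- start(subject)
    se <- end(subject)
    vapply(seq_along(query), function(i)
        sum(sc == qc[i] & ss <= qe[i] & se >= qs[i]), integer(1))
}

## random unstranded interval set on two chromosomes
randomIntervals <- function(n, maxPos = 1e5, width = c(50, 500)) {
    w <- sample(width[1]:width[2], n, replace = TRUE)
    s <- sample.int(maxPos - max(w), n, replace = TRUE)
    GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
            IRanges(s, width = w))
}

## independent classification oracle mirroring the documented label rules
bruteClassify <- function(control, clone1, clone2) {
    r1 <- bruteOverlapAny(clone1, clone2)
    repl <- clone1[r1]
    list(
        common_clone = repl[bruteOverlapAny(repl, control)],
        unique_condition = repl[!bruteOverlapAny(repl, control)],
        unreplicated = c(clone1[!r1], clone2[!bruteOverlapAny(clone2, clone1)]),
        unique_control = control[!(bruteOverlapAny(control, clone1) |
                                   bruteOverlapAny(control, clone2))],
        common_control = control[bruteOverlapAny(control, clone1) |
                                 bruteOverlapAny(control, clone2)])
}

## planted 5-block binary matrix with independent bit flips; block
## prototypes are 3-hot codes with pairwise intersection <= 1
plantedBinaryBlocks <- function(nRow = 1000L, nCol = 8L, k = 5L,
                                flip = 0.05) {
    codes <- list(c(1L, 2L, 3L), c(1L, 4L, 5L), c(2L, 4L, 6L),
                  c(3L, 5L, 6L), c(6L, 7L, 8L))
    proto <- matrix(0L, k, nCol)
    for (i in seq_len(k)) proto[i, codes[[i]]] <- 1L
    truth <- rep(seq_len(k), length.out = nRow)
    m <- proto[truth, , drop = FALSE]
    flips <- matrix(runif(length(m)) < flip, nrow(m), ncol(m))
    m <- abs(m - as.integer(flips))
    rownames(m) <- paste0("r", seq_len(nRow))
    list(matrix = m, truth = truth)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## small constant-coverage fixture: fragments tiling a toy chromosome
constantCoverageTrack <- function(covPerBase = 4L, chromLen = 60000L,
                                  fragLen = 100L) {
    starts <- seq(1L, chromLen, by = fragLen)
    gr <- GRanges("chr1", IRanges(rep(starts, covPerBase), width = fragLen))
    gr <- gr[end(gr) <= chromLen]
    computeCoverage(gr, c(chr1 = chromLen))
}

## per-base metagene oracle: loops over bases, assigns bins by the
## documented boundary formula, averages by covered width
bruteMetageneGene <- function(covVec, geneStart, geneEnd, strandChar,
                              B, flank, totalMapped) {
    L <- geneEnd - geneStart + 1L
    chromLen <- length(covVec)
    bound <- function(W) floor(W * (0:B) / B + 0.5)
    segs <- list(
        lo = (geneStart - 1L - flank) + bound(flank),
        body = (geneStart - 1L) + bound(L),
        hi = geneEnd + bound(flank))
    vals <- numeric(0)
    for (sg in segs) {
        for (i in seq_len(B)) {
            a <- sg[i]; b <- sg[i + 1L]          # 0-based half-open
            a2 <- max(a, 0L); b2 <- min(b, chromLen)
            w <- b2 - a2
            v <- if (w > 0) {
                s <- sum(covVec[(a2 + 1L):b2])
                s / ((w / 1e3) * (totalMapped / 1e7))
            } else 0
            vals <- c(vals, v)
        }
    }
    if (strandChar == "-") vals <- rev(vals)
    vals
}
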