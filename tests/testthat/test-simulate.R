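## small-but-faithful configuration used across generator tests;
## dots override the downsized defaults
tinyConfig <- function(seed = 5, ...) {
    args <- list(seed = seed,
        primary = list(label = "hs", prefix = "hs_",
                       chromLengths = c(chr1 = 1.5e6, chr2 = 1.5e6)),
        nGenes = 100L, nDomains = 80L, nEnhancers = 40L,
        nK27mGeneBody = 30L, depth = 3e4)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(simulationConfig, args)
}

test_that("config validation enforces the documented ranges", {
    expect_error(simulationConfig(spikeFraction = 0), "spikeFraction")
    expect_error(simulationConfig(reduction = c(H3K27me3 = 1.2)), "0, 1")
    expect_error(simulationConfig(depth = 0), "depth")
    expect_error(simulationConfig(retainedFraction = 1.5), "retainedFraction")
})

test_that("the toy genome is deterministic and genes are disjoint", {
    cfg <- tinyConfig()
    g1 <- makeGenome(cfg)
    g2 <- makeGenome(cfg)
    expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
    expect_identical(g1$expression, g2$expression)
    ## pairwise-disjoint placement (overlap scan oracle)
    expect_identical(sum(bruteOverlapCount(g1$genes, g1$genes)),
                     length(g1$genes))  # each gene overlaps only itself
    ## zero genes is a valid degenerate genome
    g0 <- makeGenome(tinyConfig(nGenes = 0L, nDomains = 10L,
                                retainedFraction = 0,
                                marks = "H3K27me3", nEnhancers = 0L))
    expect_identical(length(g0$genes), 0L)
    ## impossible placement errors out with advice
    expect_error(makeGenome(simulationConfig(
        primary = list(label = "hs", prefix = "hs_",
                       chromLengths = c(chr1 = 2e5)),
        nGenes = 100L)), "longer chromosomes")
})

test_that("expression is tier-structured", {
    g <- makeGenome(tinyConfig())
    ex <- g$expression
    tier <- mcols(g$genes)$tier
    med <- tapply(ex[names(g$genes)], tier, median)
    expect_gt(med[["high"]], med[["medium"]])
    expect_gt(med[["medium"]], med[["low"]])
})

test_that("planted truth carries the co-localization structure", {
    cfg <- tinyConfig()
    g <- makeGenome(cfg)
    tr <- buildTruth(g, cfg)
    expect_setequal(names(tr$domains),
                    c("H3K27me3", "Ezh2", "H3.3K27M", "H3K4me1", "input"))
    ## within-mark domains are disjoint
    for (mk in c("H3K27me3", "Ezh2", "H3.3K27M", "H3K4me1")) {
        d <- tr$domains[[mk]]
        expect_identical(sum(bruteOverlapCount(d, d)), length(d))
    }
    ## poised enhancers carry H3K4me1 and (low) H3K27me3
    poised <- tr$regions$poised_enhancers
    expect_true(all(bruteOverlapAny(poised, tr$domains$H3K4me1)))
    expect_true(all(bruteOverlapAny(poised, tr$domains$H3K27me3)))
    ## retained promoters carry no H3.3K27M
    expect_false(any(bruteOverlapAny(tr$regions$retained_promoters,
                                     tr$domains$H3.3K27M)))
    ## all truth intervals respect chromosome bounds
    lens <- chromLengths(g$layout)
    for (mk in names(tr$domains)) {
        d <- tr$domains[[mk]]
        if (!length(d)) next
        expect_true(all(end(d) <= lens[as.character(seqnames(d))]))
        expect_true(all(start(d) >= 1L))
    }
})

test_that("samples have exact depth and binomially consistent spike counts", {
    cfg <- tinyConfig()
    g <- makeGenome(cfg)
    tr <- buildTruth(g, cfg)
    s <- simulateSample(g$layout, tr, "H3K27me3", "control", cfg, seed = 9)
    expect_identical(length(s), as.integer(cfg$depth))
    nSpike <- sum(startsWith(as.character(seqnames(s)), "dm_"))
    k <- cfg$depth * cfg$spikeFraction
    ci <- qbinom(c(0.005, 0.995), cfg$depth, cfg$spikeFraction)
    expect_gte(nSpike, ci[1])
    expect_lte(nSpike, ci[2])
    ## same seed -> byte-identical fragments
    s2 <- simulateSample(g$layout, tr, "H3K27me3", "control", cfg, seed = 9)
    expect_identical(as.data.frame(s), as.data.frame(s2))
    expect_error(simulateSample(g$layout, tr, "H3K9me3", "control", cfg),
                 "not in truth")
})

test_that("background fragment starts are uniform (chi-square, fold = 1)", {
    cfg <- tinyConfig(marks = c("input"))
    g <- makeGenome(cfg)
    tr <- buildTruth(g, cfg)
    s <- simulateSample(g$layout, tr, "input", "control", cfg, seed = 17)
    st <- start(s)[as.character(seqnames(s)) == "hs_chr1"]
    len <- chromLengths(g$layout)[["chr1"]]
    obs <- table(cut(st, breaks = seq(0, len, length.out = 21)))
    p <- suppressWarnings(chisq.test(obs)$p.value)
    expect_gt(p, 0.001)
})

test_that("the planted reduction is recovered from in-domain fragments", {
    for (f in c(0.3, 0.5)) {
        cfg <- tinyConfig(seed = 23, marks = "H3K27me3",
                          retainedFraction = 0,
                          reduction = c(H3K27me3 = f), depth = 1e5)
        g <- makeGenome(cfg)
        tr <- buildTruth(g, cfg)
        ctrl <- simulateSample(g$layout, tr, "H3K27me3", "control", cfg,
                               seed = 31)
        cond <- simulateSample(g$layout, tr, "H3K27me3", "condition", cfg,
                               seed = 32)
        dom <- tr$domains$H3K27me3
        prC <- splitByOrganism(ctrl, g$layout)$hs
        prM <- splitByOrganism(cond, g$layout)$hs
        spC <- length(splitByOrganism(ctrl, g$layout)$dm)
        spM <- length(splitByOrganism(cond, g$layout)$dm)
        r <- (countOverlaps(dom, prM, ignore.strand = TRUE) / spM) /
             (countOverlaps(dom, prC, ignore.strand = TRUE) / spC)
        expect_lt(abs(median(r) - f), 0.1 * f)
    }
})

test_that("datasets round-trip through disk and hashes track the config", {
    cfg <- tinyConfig(seed = 3, depth = 5e3,
                      marks = c("H3K27me3", "input"))
    ds <- simulateDataset(cfg)
    dir <- file.path(tempdir(), "chiprx-ds-test")
    unlink(dir, recursive = TRUE)
    man <- writeDataset(ds, dir)
    expect_identical(man$seed, 3L)
    ## refusing to clobber
    expect_error(writeDataset(ds, dir), "not empty")
    expect_silent(writeDataset(ds, dir, overwrite = TRUE))
    back <- loadDataset(dir)
    nm <- "H3K27me3_control"
    orig <- ds$samples[[nm]]
    expect_identical(as.character(seqnames(back$samples[[nm]])),
                     as.character(seqnames(orig)))
    expect_identical(start(back$samples[[nm]]), start(orig))
    expect_identical(end(back$samples[[nm]]), end(orig))
    expect_identical(as.character(strand(back$samples[[nm]])),
                     as.character(strand(orig)))
    ## truth peak count on disk equals the planted count
    expect_identical(length(back$truth$H3K27me3),
                     length(ds$truth$domains$H3K27me3))
    expect_identical(back$expression, ds$genome$expression)
    ## hash changes iff the configuration changes
    expect_identical(configHash(cfg), configHash(tinyConfig(seed = 3,
        depth = 5e3, marks = c("H3K27me3", "input"))))
    expect_false(configHash(cfg) == configHash(tinyConfig(seed = 4,
        depth = 5e3, marks = c("H3K27me3", "input"))))
    unlink(dir, recursive = TRUE)
})

test_that("a full dataset is reproducible end to end under one seed", {
    cfg <- tinyConfig(seed = 13, depth = 4e3,
                      marks = c("H3K27me3", "input"))
    d1 <- simulateDataset(cfg)
    d2 <- simulateDataset(cfg)
    expect_identical(names(d1$samples), names(d2$samples))
    for (nm in names(d1$samples))
        expect_identical(as.data.frame(d1$samples[[nm]]),
                         as.data.frame(d2$samples[[nm]]))
})
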