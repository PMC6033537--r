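makeCovFromFragments <- function(fr, chromLen)
    computeCoverage(fr, c(chr1 = chromLen))

test_that("no domains are called when sample equals control", {
    set.seed(61)
    fr <- GRanges("chr1", IRanges(sample.int(2e5 - 200L, 20000,
                                             replace = TRUE), width = 100))
    cov <- makeCovFromFragments(fr, 2e5)
    expect_identical(length(callEnrichmentDomains(cov, cov)), 0L)
})

test_that("zero-depth sample yields an empty set with a warning", {
    empty <- computeCoverage(GRanges(), c(chr1 = 1e4))
    ctrl <- constantCoverageTrack()
    expect_warning(d <- callEnrichmentDomains(empty, ctrl), "zero-depth")
    expect_identical(length(d), 0L)
})

test_that("a planted high-fold domain is recovered nearly in full", {
    set.seed(62)
    chromLen <- 2e5
    nBg <- 20000                               # bg ~ 20 fragments / window
    bg <- GRanges("chr1", IRanges(sample.int(chromLen - 200L, nBg,
                                             replace = TRUE), width = 100))
    domain <- c(100001L, 103000L)
    nDom <- round(nBg * 10 * diff(domain) / chromLen)   # 10x background
    dom <- GRanges("chr1", IRanges(sample(domain[1]:(domain[2] - 100L),
                                          nDom, replace = TRUE), width = 100))
    ctrl <- GRanges("chr1", IRanges(sample.int(chromLen - 200L, nBg,
                                               replace = TRUE), width = 100))
    called <- callEnrichmentDomains(makeCovFromFragments(c(bg, dom), chromLen),
                                    makeCovFromFragments(ctrl, chromLen))
    expect_identical(length(called), 1L)
    planted <- GRanges("chr1", IRanges(domain[1], domain[2]))
    ov <- width(GenomicRanges::pintersect(called, planted))
    expect_gte(ov / width(planted), 0.9)
})

test_that("the caller is quiet under the null across seeded replicates", {
    nCalls <- vapply(1:15, function(s) {
        set.seed(1000 + s)
        fr <- GRanges("chr1", IRanges(sample.int(1e5 - 200L, 10000,
                                                 replace = TRUE),
                                      width = 100))
        ctrl <- GRanges("chr1", IRanges(sample.int(1e5 - 200L, 10000,
                                                   replace = TRUE),
                                        width = 100))
        length(callEnrichmentDomains(makeCovFromFragments(fr, 1e5),
                                     makeCovFromFragments(ctrl, 1e5)))
    }, integer(1))
    expect_gte(mean(nCalls == 0L), 14 / 15)
})

test_that("peak classification follows the stated label rules", {
    control <- GRanges("chr1", IRanges(c(101, 901), c(200, 950)))
    clone1 <- GRanges("chr1", IRanges(c(151, 501, 2001), c(250, 600, 2100)))
    clone2 <- GRanges("chr1", IRanges(c(181, 551), c(300, 650)))
    cl <- classifyPeaks(control, clone1, clone2)
    lab <- setNames(as.character(mcols(cl)$label),
                    paste(start(cl), mcols(cl)$origin))
    expect_identical(lab[["151 clone1"]], "common")
    expect_identical(lab[["501 clone1"]], "unique_condition")
    expect_identical(lab[["2001 clone1"]], "unreplicated")
    expect_identical(lab[["901 control"]], "unique_control")
    expect_identical(lab[["101 control"]], "common")
    ## exhaustive partition: every universe member is labelled exactly once
    expect_identical(length(cl), length(clone1) + length(control) +
                     sum(!bruteOverlapAny(clone2, clone1)))
})

test_that("classification matches the brute-force oracle on random sets", {
    for (s in 1:5) {
        set.seed(300 + s)
        control <- randomIntervals(200)
        clone1 <- randomIntervals(200)
        clone2 <- randomIntervals(200)
        cl <- classifyPeaks(control, clone1, clone2)
        oracle <- bruteClassify(control, clone1, clone2)
        tab <- table(mcols(cl)$label)
        expect_identical(unname(tab[["common"]]),
                         length(oracle$common_clone) +
                         length(oracle$common_control))
        expect_identical(unname(tab[["unique_condition"]]),
                         length(oracle$unique_condition))
        expect_identical(unname(tab[["unique_control"]]),
                         length(oracle$unique_control))
        expect_identical(unname(tab[["unreplicated"]]),
                         length(oracle$unreplicated))
        ## label counts invariant to input order
        perm <- sample(length(clone1))
        cl2 <- classifyPeaks(control, clone1[perm], clone2)
        expect_identical(table(mcols(cl2)$label), tab)
    }
})

test_that("swapping the clones preserves the replicated and control sets", {
    set.seed(71)
    control <- randomIntervals(150)
    clone1 <- randomIntervals(150)
    clone2 <- randomIntervals(150)
    a <- classifyPeaks(control, clone1, clone2)
    b <- classifyPeaks(control, clone2, clone1)
    sel <- function(x) x[mcols(x)$label %in% c("common", "unique_condition") &
                         mcols(x)$origin == "clone1"]
    ra <- sel(a); rb <- sel(b)
    ## anchors are clone-1 intervals, so the two runs report different
    ## coordinates for the same replicated loci: every anchor must have a
    ## replicated counterpart overlapping it in the swapped run
    expect_true(all(bruteOverlapAny(ra, rb)))
    expect_true(all(bruteOverlapAny(rb, ra)))
    ## control-side labels are fully symmetric
    ctrlLab <- function(x) as.character(mcols(x)$label[
        mcols(x)$origin == "control"])
    expect_identical(ctrlLab(a), ctrlLab(b))
})

test_that("promoter windows and assignment follow the TSS rules", {
    g <- GRanges("chr1", IRanges(c(5001, 9001), width = 1000),
                 strand = c("+", "-"))
    names(g) <- c("gp", "gm")
    pr <- promoterWindows(g, 2000, 500)
    expect_identical(start(pr["gp"]), 3001L)   # TSS-2000
    expect_identical(end(pr["gp"]), 5500L)     # TSS+500-1
    expect_identical(end(pr["gm"]), 12000L)    # minus strand: TSS = end
    expect_identical(start(pr["gm"]), 9501L)
    ## peak inside the window -> included; bookended peak -> excluded
    expect_identical(assignPromoters(GRanges("chr1", IRanges(3500, 3600)), pr),
                     "gp")
    bookend <- GRanges("chr1", IRanges(2901, 3000))  # BED end == window start
    expect_identical(assignPromoters(bookend, pr), character(0))
})

test_that("promoter assignment matches the pairwise oracle", {
    set.seed(81)
    g <- GRanges("chr1", IRanges(seq(5000, by = 1500, length.out = 50),
                                 width = 800),
                 strand = sample(c("+", "-"), 50, TRUE))
    names(g) <- sprintf("g%02d", 1:50)
    pr <- promoterWindows(g)
    peaks <- randomIntervals(100, maxPos = 9e4)
    expect_identical(assignPromoters(peaks, pr),
                     sort(names(pr)[bruteOverlapAny(pr, peaks)]))
})

test_that("venn region counts satisfy inclusion-exclusion", {
    v <- vennCounts(list(A = c("A", "B"), B = c("B", "C"), C = "B"))
    expect_identical(v$count[v$A & v$B & v$C], 1L)      # element B
    expect_identical(sum(v$count), 3L)                  # |union|
    d <- vennCounts(list(x = letters[1:3], y = letters[4:6]))
    expect_identical(d$count[d$x & d$y], 0L)
    expect_error(vennCounts(list(A = 1)), "at least 2")
    expect_error(vennCounts(setNames(list(1:2, 2:3), c("A", "A"))), "unique")
    set.seed(91)
    sets <- lapply(1:3, function(i) sample(sprintf("e%03d", 1:150), 100))
    names(sets) <- c("s1", "s2", "s3")
    v3 <- vennCounts(sets)
    expect_identical(sum(v3$count), length(unique(unlist(sets))))
    ## every region count equals the direct set-algebra computation
    for (r in seq_len(nrow(v3))) {
        inSets <- names(sets)[unlist(v3[r, names(sets)])]
        outSets <- setdiff(names(sets), inSets)
        region <- Reduce(intersect, sets[inSets])
        for (o in outSets) region <- setdiff(region, sets[[o]])
        expect_identical(v3$count[r], length(region))
    }
})

test_that("initiating-set construction is the documented set algebra", {
    expect_identical(
        buildInitiatingSet(c("P1", "P2", "P3"), c("P2", "P3", "P4"),
                           c("P3", "P5")),
        c("P2", "P3", "P5"))
    refA <- c("a", "b", "c"); refB <- c("b", "c", "d")
    expect_identical(buildInitiatingSet(refA, refB, c("b", "c")),
                     c("b", "c"))   # sample inside refA n refB
    expect_identical(buildInitiatingSet(character(0), character(0),
                                        c("x", "y")), c("x", "y"))
})
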