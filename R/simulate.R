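## run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Synthetic-dataset configuration
#'
#' Parameters of the seeded toy-data generator. Defaults emulate the study
#' conditions every downstream stage assumes: a two-organism fragment
#' mixture with a 2\% spike-in proportion, Poisson background coverage with
#' planted broad enrichment domains per mark, a condition-level global
#' reduction of H3K27me3/Ezh2, per-gene expression tiers correlated with
#' H3.3K27M occupancy, and fixed sequencing depth per sample.
#'
#' @param seed integer RNG seed.
#' @param primary,spikein organism descriptors: lists with \code{label},
#'   \code{prefix} and named \code{chromLengths} (bp).
#' @param nGenes number of non-overlapping genes placed on the primary
#'   genome.
#' @param geneLengthRange min/max gene length in bp.
#' @param expressionMeanlog,expressionSdlog log-normal expression model per
#'   tier (high/medium/low) and its common sdlog.
#' @param marks marks to simulate.
#' @param nDomains number of planted H3K27me3 domains.
#' @param domainWidth width of a planted H3K27me3 domain in bp.
#' @param foldEnrichment named per-mark fold enrichment of in-domain over
#'   background intensity.
#' @param reduction named condition-level global reduction factor f in
#'   (0, 1] applied to in-domain intensity of the named marks in the
#'   condition (mutant) samples.
#' @param retainedFraction fraction of H3K27me3 domains planted as
#'   "retained" promoter domains (strong PRC2 sites at promoters of
#'   low-expression genes) that largely escape the global reduction.
#' @param retainedReduction reduction factor f of retained domains.
#' @param nEnhancers,poisedFraction,enhancerWidth enhancer structure:
#'   poised enhancers carry H3K4me1 plus low H3K27me3 and, in the
#'   condition, redistributed Ezh2 and H3.3K27M.
#' @param poisedK27me3Fold fold enrichment of the low H3K27me3 signal at
#'   poised enhancers.
#' @param nK27mGeneBody number of high-expression gene bodies carrying
#'   H3.3K27M domains.
#' @param k27mAtReducedFold fold of H3.3K27M at non-retained H3K27me3
#'   domains.
#' @param spikeFraction spike-in proportion of the control sample's
#'   fragment mixture (the experiment adds spike chromatin at 1--5\%).
#' @param depth fragments per sample after fixed-depth resampling.
#' @param fragLen fragment (template) length in bp.
#' @return validated configuration list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(
        seed = 1L,
        primary = list(label = "hs", prefix = "hs_",
                       chromLengths = c(chr1 = 3e6, chr2 = 3e6)),
        spikein = list(label = "dm", prefix = "dm_",
                       chromLengths = c(chr2L = 5e5)),
        nGenes = 200L,
        geneLengthRange = c(2000L, 8000L),
        expressionMeanlog = c(high = 5, medium = 3, low = 1),
        expressionSdlog = 0.5,
        marks = c("H3K27me3", "Ezh2", "H3.3K27M", "H3K4me1", "input"),
        nDomains = 200L,
        domainWidth = 10000L,
        foldEnrichment = c(H3K27me3 = 30, Ezh2 = 20, H3.3K27M = 10,
                           H3K4me1 = 10),
        reduction = c(H3K27me3 = 0.3, Ezh2 = 0.5),
        retainedFraction = 0.25,
        retainedReduction = 0.9,
        nEnhancers = 100L,
        poisedFraction = 0.6,
        enhancerWidth = 2000L,
        poisedK27me3Fold = 5,
        nK27mGeneBody = 60L,
        k27mAtReducedFold = 8,
        spikeFraction = 0.02,
        depth = 1e5,
        fragLen = 200L) {
    cfg <- list(seed = as.integer(seed), primary = primary, spikein = spikein,
        nGenes = as.integer(nGenes), geneLengthRange = geneLengthRange,
        expressionMeanlog = expressionMeanlog,
        expressionSdlog = expressionSdlog, marks = marks,
        nDomains = as.integer(nDomains), domainWidth = as.integer(domainWidth),
        foldEnrichment = foldEnrichment, reduction = reduction,
        retainedFraction = retainedFraction,
        retainedReduction = retainedReduction,
        nEnhancers = as.integer(nEnhancers), poisedFraction = poisedFraction,
        enhancerWidth = as.integer(enhancerWidth),
        poisedK27me3Fold = poisedK27me3Fold,
        nK27mGeneBody = as.integer(nK27mGeneBody),
        k27mAtReducedFold = k27mAtReducedFold,
        spikeFraction = spikeFraction, depth = depth,
        fragLen = as.integer(fragLen))
    if (cfg$spikeFraction <= 0 || cfg$spikeFraction >= 1)
        stop("spikeFraction must be in (0, 1)")
    if (any(cfg$reduction <= 0) || any(cfg$reduction > 1) ||
        cfg$retainedReduction <= 0 || cfg$retainedReduction > 1)
        stop("reduction factors must be in (0, 1]")
    if (cfg$depth <= 0) stop("depth must be > 0")
    if (cfg$retainedFraction < 0 || cfg$retainedFraction > 1)
        stop("retainedFraction must be in [0, 1]")
    if (any(cfg$foldEnrichment < 1)) stop("foldEnrichment must be >= 1")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig (seed", x$seed, ")\n")
    cat(sprintf("  primary %s: %.3g bp; spikein %s: %.3g bp; spike fraction %.3g\n",
        x$primary$label, sum(x$primary$chromLengths), x$spikein$label,
        sum(x$spikein$chromLengths), x$spikeFraction))
    cat(sprintf("  %d genes; %d H3K27me3 domains (fold %g, f %g, retained %g at f %g)\n",
        x$nGenes, x$nDomains, x$foldEnrichment[["H3K27me3"]],
        x$reduction[["H3K27me3"]], x$retainedFraction, x$retainedReduction))
    cat(sprintf("  depth %g fragments/sample, fragment length %d bp\n",
        x$depth, x$fragLen))
    invisible(x)
}

## layout from a config
.layoutFromConfig <- function(config) {
    GenomeLayout(config$primary$label, config$spikein$label,
        chromLengths = setNames(
            list(config$primary$chromLengths, config$spikein$chromLengths),
            c(config$primary$label, config$spikein$label)),
        prefixes = setNames(c(config$primary$prefix, config$spikein$prefix),
            c(config$primary$label, config$spikein$label)))
}

.makeGenome <- function(config) {
    layout <- .layoutFromConfig(config)
    lens <- config$primary$chromLengths
    n <- config$nGenes
    margin <- 12000L; minGap <- 200L
    perChrom <- if (n > 0) {
        p <- as.vector(rmultinom(1, n, prob = lens / sum(lens)))
        setNames(p, names(lens))
    } else setNames(integer(length(lens)), names(lens))
    grl <- list()
    for (ch in names(lens)) {
        nc <- perChrom[[ch]]
        if (nc == 0L) next
        gl <- round(runif(nc, config$geneLengthRange[1],
                          config$geneLengthRange[2]))
        avail <- lens[[ch]] - 2 * margin
        extra <- avail - sum(gl) - (nc + 1) * minGap
        if (extra < 0)
            stop("genes cannot fit without overlap on ", ch,
                 "; use longer chromosomes or fewer/shorter genes")
        props <- diff(c(0, sort(runif(nc)), 1))
        gaps <- minGap + extra * props
        starts0 <- margin + round(cumsum(gaps[seq_len(nc)]) +
                                  cumsum(c(0, gl[-nc])))
        gch <- GRanges(ch, IRanges(starts0 + 1L, width = gl),
                       strand = sample(c("+", "-"), nc, replace = TRUE))
        seqlevels(gch) <- names(lens)
        grl[[ch]] <- gch
    }
    genes <- if (length(grl)) sort(do.call(c, unname(grl))) else
        GRanges()
    seqlevels(genes) <- names(lens)
    seqlengths(genes) <- lens
    if (length(genes)) {
        names(genes) <- sprintf("g%04d", seq_along(genes))
        tier <- sample(rep(c("high", "medium", "low"),
                           length.out = length(genes)))
        mcols(genes)$tier <- factor(tier, levels = c("high", "medium", "low"))
        expr <- rlnorm(length(genes),
                       meanlog = config$expressionMeanlog[tier],
                       sdlog = config$expressionSdlog)
        expression <- setNames(expr, names(genes))
    } else expression <- setNames(numeric(0), character(0))
    list(layout = layout, genes = genes, expression = expression)
}

#' Generate a toy genome, gene models and expression table
#'
#' Places non-overlapping genes on the primary chromosomes, assigns each
#' gene an expression tier, and draws log-normal expression per tier.
#' Deterministic given \code{config$seed}.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{layout} ([GenomeLayout-class]), \code{genes}
#'   (named \code{GRanges} with a \code{tier} column) and \code{expression}
#'   (named numeric).
#' @export
makeGenome <- function(config) .withSeed(config$seed, .makeGenome(config))

## place n non-overlapping intervals of width w inside `free` (GRanges of
## unoccupied space), consuming the free space as it goes
.placeIntervals <- function(free, n, w, what = "domains") {
    out <- GRanges()
    for (i in seq_len(n)) {
        ok <- width(free) >= w + 200L
        if (!any(ok))
            stop("cannot place ", what,
                 ": primary chromosomes too short or too crowded")
        cand <- which(ok)
        pick <- cand[sample.int(length(cand), 1L,
                                prob = width(free)[cand] - w)]
        off <- sample.int(width(free)[pick] - w + 1L, 1L) - 1L
        iv <- GRanges(seqnames(free)[pick],
                      IRanges(start(free)[pick] + off, width = w))
        seqlevels(iv) <- seqlevels(free)
        out <- c(out, iv)
        free <- setdiff(free, iv + 100L)
    }
    list(placed = out, free = free)
}

.domainRow <- function(gr, role, fold, fCtrl, fCond, presCtrl, presCond) {
    if (length(gr) == 0L) return(GRanges())
    gr <- granges(gr)
    strand(gr) <- "*"
    mcols(gr) <- NULL
    names(gr) <- NULL
    mcols(gr)$role <- role
    mcols(gr)$fold <- fold
    mcols(gr)$f_control <- fCtrl
    mcols(gr)$f_condition <- fCond
    mcols(gr)$present_control <- presCtrl
    mcols(gr)$present_condition <- presCond
    gr
}

.buildTruth <- function(genome, config) {
    layout <- genome$layout
    genes <- genome$genes
    lens <- chromLengths(layout, primaryOrganism(layout))
    chromGR <- GRanges(names(lens), IRanges(1L, width = lens))
    occupied <- suppressWarnings(trim(granges(genes) + 3000L))
    strand(occupied) <- "*"
    free <- setdiff(chromGR, reduce(occupied))
    hasEnh <- "H3K4me1" %in% config$marks
    nRet <- round(config$nDomains * config$retainedFraction)
    nOther <- config$nDomains - nRet
    ## retained promoter domains must not overlap a neighbouring gene or
    ## promoter, so restrict to low-tier genes with isolated promoters
    promAll <- promoterWindows(genes, 2000L, 500L)
    isolated <- countOverlaps(promAll, granges(genes),
                              ignore.strand = TRUE) == 1L &
        countOverlaps(promAll, promAll, ignore.strand = TRUE) == 1L
    lowGenes <- genes[mcols(genes)$tier == "low" & isolated]
    if (nRet > length(lowGenes))
        stop("retainedFraction requires more isolated low-tier genes than available")
    retGenes <- sort(sample(names(lowGenes), nRet))
    retained <- promoterWindows(genes[retGenes], 2000L, 500L)
    pl <- .placeIntervals(free, nOther, config$domainWidth,
                          "H3K27me3 domains")
    otherDom <- pl$placed
    free <- pl$free
    poised <- GRanges(); active <- GRanges()
    if (hasEnh) {
        nPoised <- round(config$nEnhancers * config$poisedFraction)
        pl <- .placeIntervals(free, config$nEnhancers, config$enhancerWidth,
                              "enhancers")
        enh <- pl$placed
        idx <- sample.int(length(enh), nPoised)
        poised <- enh[sort(idx)]
        active <- enh[sort(setdiff(seq_along(enh), idx))]
    }
    foldOf <- function(mark) config$foldEnrichment[[mark]]
    fOf <- function(mark) {
        if (mark %in% names(config$reduction)) config$reduction[[mark]] else 1
    }
    domains <- list()
    if ("H3K27me3" %in% config$marks || "Ezh2" %in% config$marks ||
        "H3.3K27M" %in% config$marks) {
        domains$H3K27me3 <- sort(c(
            .domainRow(retained, "retained_promoter", foldOf("H3K27me3"),
                       1, config$retainedReduction, TRUE, TRUE),
            .domainRow(otherDom, "k27me3_domain", foldOf("H3K27me3"),
                       1, fOf("H3K27me3"), TRUE, TRUE),
            .domainRow(poised, "poised_k27me3", config$poisedK27me3Fold,
                       1, fOf("H3K27me3"), TRUE, TRUE)))
    }
    if ("Ezh2" %in% config$marks) {
        ## redistribution: Ezh2 persists at strong PRC2 promoters, leaves
        ## the bulk domains, and gains condition-only poised-enhancer sites
        domains$Ezh2 <- sort(c(
            .domainRow(retained, "retained_promoter", foldOf("Ezh2"),
                       1, fOf("Ezh2"), TRUE, TRUE),
            .domainRow(otherDom, "k27me3_domain", foldOf("Ezh2"),
                       1, 1, TRUE, FALSE),
            .domainRow(poised, "poised_enhancer", foldOf("Ezh2"),
                       1, 1, FALSE, TRUE)))
    }
    if ("H3.3K27M" %in% config$marks) {
        highGenes <- genes[mcols(genes)$tier == "high"]
        nBody <- min(config$nK27mGeneBody, length(highGenes))
        bodyGenes <- sort(sample(names(highGenes), nBody))
        domains$H3.3K27M <- sort(c(
            .domainRow(granges(genes[bodyGenes]), "active_gene_body",
                       foldOf("H3.3K27M"), 1, 1, FALSE, TRUE),
            .domainRow(poised, "poised_enhancer", foldOf("H3.3K27M"),
                       1, 1, FALSE, TRUE),
            .domainRow(otherDom, "k27me3_domain", config$k27mAtReducedFold,
                       1, 1, FALSE, TRUE)))
    }
    if (hasEnh) {
        domains$H3K4me1 <- sort(c(
            .domainRow(poised, "poised_enhancer", foldOf("H3K4me1"),
                       1, 1, TRUE, TRUE),
            .domainRow(active, "active_enhancer", foldOf("H3K4me1"),
                       1, 1, TRUE, TRUE)))
    }
    if ("input" %in% config$marks)
        domains$input <- .domainRow(GRanges(), character(0), numeric(0),
                                    numeric(0), numeric(0), logical(0),
                                    logical(0))
    for (mk in names(domains)) {
        seqlevels(domains[[mk]]) <- names(lens)
        seqlengths(domains[[mk]]) <- lens
        if (length(domains[[mk]]))
            names(domains[[mk]]) <- sprintf("%s_dom_%04d", mk,
                                            seq_along(domains[[mk]]))
    }
    list(domains = domains,
         regions = list(retained_promoters = retained,
                        k27me3_domains = otherDom,
                        poised_enhancers = poised,
                        active_enhancers = active,
                        retained_genes = retGenes))
}

#' Plant the truth structure of a synthetic dataset
#'
#' Builds per-mark planted enrichment domains and the co-localization
#' structure downstream stages are expected to recover: retained promoter
#' domains (strong PRC2 sites at low-expression genes, escaping most of the
#' global H3K27me3 reduction and carrying no H3.3K27M), bulk H3K27me3
#' domains subject to the full reduction, poised enhancers (H3K4me1 plus
#' low H3K27me3, gaining condition-only Ezh2 and H3.3K27M), active
#' enhancers, and H3.3K27M domains over high-expression gene bodies.
#'
#' @param genome output of [makeGenome()].
#' @param config the same [simulationConfig()].
#' @return list with \code{domains} (per-mark \code{GRanges} with columns
#'   \code{role}, \code{fold}, \code{f_control}, \code{f_condition},
#'   \code{present_control}, \code{present_condition}) and \code{regions}
#'   (the planted structural region sets).
#' @export
buildTruth <- function(genome, config)
    .withSeed(config$seed + 1L, .buildTruth(genome, config))

## per-chromosome background/domain segmentation for one mark+condition
.segmentsFor <- function(layout, dom, condition, config) {
    if (length(dom)) {
        pres <- mcols(dom)[[paste0("present_", condition)]]
        f <- mcols(dom)[[paste0("f_", condition)]]
        if (any(f[pres] <= 0 | f[pres] > 1))
            stop("reduction factor f outside (0, 1]")
        dom <- dom[pres]
        wgt <- mcols(dom)$fold * f[pres]
    } else {
        wgt <- numeric(0)
    }
    lens <- chromLengths(layout, primaryOrganism(layout))
    segs <- list()
    for (ch in names(lens)) {
        sel <- as.character(seqnames(dom)) == ch
        ## run-length view of the per-base weight; overlapping domains
        ## (not produced by the default truth) add their excess weights
        r <- Rle(1, lens[[ch]])
        if (any(sel)) {
            d <- dom[sel]
            r <- r + coverage(IRanges(start(d), end(d)),
                              weight = wgt[sel] - 1, width = lens[[ch]])
        }
        segs[[ch]] <- data.frame(chrom = ch,
                                 start1 = cumsum(c(1, runLength(r)))[
                                     seq_along(runLength(r))],
                                 width = runLength(r),
                                 weight = runValue(r),
                                 stringsAsFactors = FALSE)
    }
    do.call(rbind, segs)
}

#' Simulate one sample's aligned fragments
#'
#' Draws \code{config$depth} fragments from a multinomial over genome
#' segments whose per-base intensity is 1 for background and
#' \code{fold * f} inside planted domains of the mark that are present in
#' the given condition; spike-in chromatin mass is held constant across
#' conditions (anchored so the control sample's expected spike proportion
#' equals \code{config$spikeFraction}), which is what lets spike-in
#' normalization expose condition-level global changes that fixed-depth
#' resampling otherwise masks. Fragment starts are uniform within segments;
#' fragments are emitted on the combined (prefixed) chromosome namespace.
#'
#' @param layout a [GenomeLayout-class].
#' @param truth output of [buildTruth()].
#' @param mark mark to simulate (must be in \code{truth$domains}).
#' @param condition \code{"control"} or \code{"condition"}.
#' @param config the [simulationConfig()].
#' @param sampleId sample name stored in the output.
#' @param seed optional seed; \code{NULL} uses the current RNG state.
#' @return fragment \code{GRanges} on the combined namespace with a
#'   \code{sample_id} column.
#' @export
simulateSample <- function(layout, truth, mark,
                           condition = c("condition", "control"),
                           config, sampleId = paste0(mark, "_", condition),
                           seed = NULL) {
    condition <- match.arg(condition)
    if (!mark %in% names(truth$domains))
        stop("mark '", mark, "' not in truth")
    run <- function() {
        dom <- truth$domains[[mark]]
        segs <- .segmentsFor(layout, dom, condition, config)
        segsCtrl <- .segmentsFor(layout, dom, "control", config)
        Pctrl <- sum(segsCtrl$width * segsCtrl$weight)
        s <- config$spikeFraction
        S <- s / (1 - s) * Pctrl
        spikeLens <- chromLengths(layout, spikeinOrganism(layout))
        spikeSegs <- data.frame(chrom = names(spikeLens), start1 = 1L,
                                width = as.numeric(spikeLens),
                                weight = S / sum(spikeLens),
                                stringsAsFactors = FALSE)
        org <- c(rep("P", nrow(segs)), rep("S", nrow(spikeSegs)))
        all <- rbind(segs, spikeSegs)
        mass <- all$width * all$weight
        counts <- as.vector(rmultinom(1L, size = config$depth,
                                      prob = mass / sum(mass)))
        prefP <- layout@prefixes[[primaryOrganism(layout)]]
        prefS <- layout@prefixes[[spikeinOrganism(layout)]]
        lensAll <- combinedSeqlengths(layout)
        nz <- which(counts > 0L)
        chroms <- character(0); starts <- integer(0); segLen <- numeric(0)
        for (i in nz) {
            st <- all$start1[i] + floor(runif(counts[i]) * all$width[i])
            pref <- if (org[i] == "P") prefP else prefS
            chroms <- c(chroms, rep(paste0(pref, all$chrom[i]), counts[i]))
            starts <- c(starts, as.integer(st))
        }
        lim <- lensAll[chroms]
        ends <- pmin(starts + config$fragLen - 1L, lim)
        gr <- GRanges(chroms, IRanges(starts, ends),
                      strand = sample(c("+", "-"), length(starts),
                                      replace = TRUE))
        seqlevels(gr) <- names(lensAll)
        seqlengths(gr) <- lensAll
        mcols(gr)$sample_id <- sampleId
        gr
    }
    if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Simulate a complete dataset
#'
#' Generates the genome, the planted truth and the full sample panel:
#' H3K27me3 and Ezh2 in control plus two condition clones, H3.3K27M in the
#' two condition clones, H3K4me1 and input in the control (for the marks
#' present in \code{config$marks}). Fully deterministic given
#' \code{config$seed}.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{genome}, \code{truth}, \code{samples} (named
#'   list of fragment \code{GRanges}), \code{sampleInfo} (data.frame) and
#'   \code{config}.
#' @export
simulateDataset <- function(config = simulationConfig()) {
    genome <- makeGenome(config)
    truth <- buildTruth(genome, config)
    plan <- list(
        H3K27me3 = c("control", "condition", "condition"),
        Ezh2 = c("control", "condition", "condition"),
        H3.3K27M = c("condition", "condition"),
        H3K4me1 = "control",
        input = "control")
    rows <- list()
    for (mk in intersect(names(plan), config$marks)) {
        conds <- plan[[mk]]
        cloneIdx <- cumsum(conds == "condition")
        for (j in seq_along(conds)) {
            nm <- if (conds[j] == "control") paste0(mk, "_control")
                  else paste0(mk, "_clone", cloneIdx[j])
            rows[[nm]] <- data.frame(sample = nm, mark = mk,
                                     condition = conds[j],
                                     stringsAsFactors = FALSE)
        }
    }
    info <- do.call(rbind, rows)
    rownames(info) <- NULL
    samples <- list()
    for (i in seq_len(nrow(info))) {
        samples[[info$sample[i]]] <- simulateSample(
            genome$layout, truth, info$mark[i], info$condition[i], config,
            sampleId = info$sample[i], seed = config$seed + 10L + i)
    }
    list(genome = genome, truth = truth, samples = samples,
         sampleInfo = info, config = config)
}
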