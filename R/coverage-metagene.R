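#' Genome-wide fragment coverage
#'
#' Per-base pileup of (deduplicated) fragments for one sample: coverage at
#' base b equals the number of fragments whose interval contains b.
#'
#' @param fragments \code{GRanges} of fragments on one organism's native
#'   namespace.
#' @param seqlen named numeric vector of chromosome lengths, or a
#'   [GenomeLayout-class] (primary organism lengths are used). Fragments
#'   extending beyond chromosome bounds are a hard error.
#' @return a [CoverageTrack-class].
#' @export
computeCoverage <- function(fragments, seqlen) {
    if (is(seqlen, "GenomeLayout"))
        seqlen <- chromLengths(seqlen, primaryOrganism(seqlen))
    bad <- setdiff(as.character(unique(seqnames(fragments))), names(seqlen))
    if (length(bad))
        stop("fragments on unknown chromosome(s): ", paste(bad, collapse = ", "))
    lim <- seqlen[as.character(seqnames(fragments))]
    if (any(end(fragments) > lim) || any(start(fragments) < 1L))
        stop("fragment beyond chromosome bounds")
    gr <- GRanges(seqnames(fragments), ranges(fragments))
    seqlevels(gr) <- names(seqlen)
    seqlengths(gr) <- seqlen
    new("CoverageTrack", cov = coverage(gr),
        totalMapped = length(fragments))
}

#' @describeIn computeCoverage the per-chromosome coverage \code{RleList}.
#' @param x a \code{CoverageTrack}.
#' @export
coverageRle <- function(x) x@cov

#' @describeIn computeCoverage fragment count behind the track.
#' @export
totalMapped <- function(x) x@totalMapped

setMethod("show", "CoverageTrack", function(object) {
    mass <- sum(vapply(object@cov,
        function(r) sum(as.numeric(runValue(r)) * runLength(r)), numeric(1)))
    cat(sprintf(
        "CoverageTrack: %d chromosome(s), %d fragments, total mass %.4g bp\n",
        length(object@cov), object@totalMapped, mass))
})

#' Reads per kilobase per 10 million mapped reads
#'
#' The density unit used throughout: \code{count / ((width/1e3) *
#' (totalMapped/1e7))}.
#'
#' @param count fragment count (or summed per-base coverage) in the region.
#' @param widthBp region width in bp (> 0).
#' @param totalMapped total mapped fragments of the sample (> 0).
#' @return normalized density; vectorized over \code{count}/\code{widthBp}.
#' @examples
#' rpk10m(10, 1000, 1e7)   # 10
#' rpk10m(25, 500, 5e6)    # 100
#' @export
rpk10m <- function(count, widthBp, totalMapped) {
    if (any(widthBp <= 0)) stop("widthBp must be > 0")
    if (any(totalMapped <= 0)) stop("totalMapped must be > 0")
    count / ((widthBp / 1e3) * (totalMapped / 1e7))
}

#' Stratify genes into expression tiers
#'
#' Genes are ranked by expression (descending) and split into \code{k}
#' contiguous rank groups of near-equal size; when sizes differ the larger
#' groups sit at the higher-expression end. Ties are broken by gene id
#' (lexicographic), making the assignment deterministic.
#'
#' @param genes \code{GRanges} of gene models, names = gene ids.
#' @param expression named numeric vector (gene id -> expression, >= 0);
#'   every gene must have a value.
#' @param k number of tiers; for the default \code{k = 3} the tiers are
#'   labelled \code{high}, \code{medium}, \code{low}.
#' @return factor of tier labels, named by gene id, in the input gene order.
#' @export
stratifyGenes <- function(genes, expression, k = 3) {
    ids <- names(genes)
    if (is.null(ids) || anyDuplicated(ids))
        stop("genes must carry unique names (gene ids)")
    missing <- ids[!ids %in% names(expression) |
                   is.na(expression[ids])]
    if (length(missing))
        stop("missing expression value for gene(s): ",
             paste(missing, collapse = ", "))
    vals <- expression[ids]
    ord <- order(-vals, ids)
    n <- length(ids)
    base <- n %/% k
    sizes <- rep(base, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- base + 1L
    labels <- if (k == 3) c("high", "medium", "low") else paste0("tier", seq_len(k))
    tier <- rep(labels, times = sizes)
    out <- factor(setNames(tier[order(ord)], ids), levels = labels)
    out
}

## strictly increasing half-up-rounded boundaries: floor(L*i/B + 0.5)
.binBoundaries <- function(L, B) floor(L * (0:B) / B + 0.5)

## per-gene 3*B bin grid in genomic order (left flank, body, right flank);
## returns data.frame(start, end) of half-open 0-based bins, possibly
## extending beyond chromosome bounds (clipped by the caller)
.geneBins <- function(start0, end0, B, flank) {
    bodyB <- start0 + .binBoundaries(end0 - start0, B)
    flankB <- .binBoundaries(flank, B)
    left <- (start0 - flank) + flankB
    right <- end0 + flankB
    data.frame(
        start = c(left[-(B + 1L)], bodyB[-(B + 1L)], right[-(B + 1L)]),
        end = c(left[-1L], bodyB[-1L], right[-1L]))
}

#' Expression-stratified metagene profile
#'
#' Average normalized density over a flank--body--flank grid: the gene body
#' (TSS to TES) is split into \code{bins} equal-fraction bins, and each
#' flank into \code{bins} fixed-width bins of \code{flank/bins} bp. Per-bin
#' summed coverage is converted to reads per kilobase per 10 million mapped
#' reads using the bin's (covered) width; minus-strand genes are reversed so
#' bin 1 is always 5'-most; tier values are unweighted means over genes.
#'
#' Genes shorter than \code{bins} bp are excluded (they cannot support
#' non-empty bins). Flank bins truncated at chromosome edges contribute
#' only their covered width; fully truncated bins contribute 0.
#'
#' @param coverage a [CoverageTrack-class].
#' @param genes \code{GRanges} gene models (names = gene ids, strand set).
#' @param tiers factor of tier labels named by gene id (see
#'   [stratifyGenes()]); an empty tier after exclusions is an error.
#' @param bins bins per segment (default 100).
#' @param flank flank width in bp (default 10000).
#' @param scaleFactor optional multiplicative scale applied to all values
#'   (default 1, plain per-sample RPK10M); pass a spike-in derived factor
#'   to put profiles from different samples on a common calibrated scale.
#' @return a [MetageneProfile-class] with a tiers x (3*bins) value matrix.
#' @export
metageneProfile <- function(coverage, genes, tiers, bins = 100L,
                            flank = 10000L, scaleFactor = 1) {
    if (scaleFactor <= 0) stop("scaleFactor must be > 0")
    bins <- as.integer(bins); flank <- as.integer(flank)
    ids <- names(genes)
    tiers <- tiers[ids]
    short <- width(genes) < bins
    if (any(short)) {
        message("excluding ", sum(short), " gene(s) shorter than ", bins, " bp")
        genes <- genes[!short]
        tiers <- tiers[!short]
        ids <- names(genes)
    }
    lvls <- levels(tiers)
    counts <- table(tiers)
    if (any(counts == 0))
        stop("empty tier(s): ", paste(lvls[counts == 0], collapse = ", "))
    N <- totalMapped(coverage)
    if (N <= 0) stop("coverage has no mapped fragments")
    covList <- coverageRle(coverage)
    chromLen <- vapply(covList, length, numeric(1))
    perGene <- matrix(0, nrow = length(genes), ncol = 3L * bins)
    for (i in seq_along(genes)) {
        ch <- as.character(seqnames(genes)[i])
        if (!ch %in% names(covList))
            stop("gene '", ids[i], "' on chromosome absent from coverage: ", ch)
        b <- .geneBins(start(genes)[i] - 1L, end(genes)[i], bins, flank)
        lo <- pmax(b$start, 0)
        hi <- pmin(b$end, chromLen[[ch]])
        w <- pmax(hi - lo, 0)
        vals <- numeric(nrow(b))
        nz <- w > 0
        if (any(nz)) {
            v <- Views(covList[[ch]], start = lo[nz] + 1L, end = hi[nz])
            vals[nz] <- rpk10m(viewSums(v), w[nz], N)
        }
        if (as.character(strand(genes)[i]) == "-") vals <- rev(vals)
        perGene[i, ] <- vals
    }
    mat <- do.call(rbind, lapply(lvls, function(tl)
        colMeans(perGene[tiers == tl, , drop = FALSE]))) * scaleFactor
    rownames(mat) <- lvls
    colnames(mat) <- c(paste0("up", seq_len(bins)), paste0("body", seq_len(bins)),
                       paste0("down", seq_len(bins)))
    new("MetageneProfile", values = mat, bins = bins, flank = flank,
        nGenes = setNames(as.integer(counts), lvls))
}

#' @describeIn metageneProfile the tier x bin value matrix.
#' @param x a \code{MetageneProfile}.
#' @export
profileMatrix <- function(x) x@values

setMethod("show", "MetageneProfile", function(object) {
    cat(sprintf("MetageneProfile: %d tier(s) x %d bins (flank %d bp)\n",
                nrow(object@values), ncol(object@values), object@flank))
    cat("  genes per tier:",
        paste(sprintf("%s=%d", names(object@nGenes), object@nGenes),
              collapse = ", "), "\n")
})

#' Plot a metagene profile
#'
#' Line plot of density across the flank--body--flank grid, one line per
#' expression tier.
#'
#' @param profile a [MetageneProfile-class].
#' @param main plot title.
#' @export
plotMetagene <- function(profile, main = "Metagene profile") {
    m <- profileMatrix(profile)
    B <- profile@bins
    graphics::matplot(t(m), type = "l", lty = 1, lwd = 2,
        xlab = "bin (flank | body | flank)", ylab = "RPK10M", main = main,
        xaxt = "n")
    graphics::axis(1, at = c(1, B, 2 * B, 3 * B),
        labels = c(sprintf("-%dkb", profile@flank %/% 1000), "TSS", "TES",
                   sprintf("+%dkb", profile@flank %/% 1000)))
    graphics::abline(v = c(B + 0.5, 2 * B + 0.5), lty = 3, col = "grey")
    graphics::legend("topright", legend = rownames(m), lty = 1, lwd = 2,
        col = seq_len(nrow(m)), bty = "n")
    invisible(NULL)
}
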