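#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- Rle runValue runLength
#' @importFrom IRanges IRanges Views viewSums RleList
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqlengths<-
#'   seqlevels<- keepSeqlevels
#' @importFrom stats ppois pt rmultinom runif rlnorm setNames median
#'   quantile var cutree hclust as.dist
#' @importFrom utils read.table write.table
NULL

#' Two-organism combined genome layout
#'
#' Describes a combined reference built from a primary organism and an
#' exogenous spike-in organism. Chromosomes of the combined namespace carry
#' an organism-specific prefix (e.g. \code{"hs_chr1"}, \code{"dm_chr2L"}),
#' so every aligned fragment can be attributed to exactly one organism.
#'
#' @slot primary label of the primary (studied) organism.
#' @slot spikein label of the spike-in (calibration) organism.
#' @slot chromLengths named list, one element per organism, each a named
#'   numeric vector of chromosome lengths in bp (native, unprefixed names).
#' @slot prefixes named character vector mapping organism label to the
#'   prefix used in the combined chromosome namespace.
#'
#' @seealso [GenomeLayout()] for the constructor, [splitByOrganism()].
#' @exportClass GenomeLayout
setClass("GenomeLayout",
    representation(
        primary = "character",
        spikein = "character",
        chromLengths = "list",
        prefixes = "character"
    )
)

setValidity("GenomeLayout", function(object) {
    msg <- character()
    orgs <- c(object@primary, object@spikein)
    if (length(object@primary) != 1L || length(object@spikein) != 1L)
        msg <- c(msg, "exactly one primary and one spikein organism required")
    if (identical(object@primary, object@spikein))
        msg <- c(msg, "primary and spikein organism labels must differ")
    if (!all(orgs %in% names(object@chromLengths)))
        msg <- c(msg, "chromLengths must have one entry per organism")
    for (org in intersect(orgs, names(object@chromLengths))) {
        len <- object@chromLengths[[org]]
        if (length(len) == 0L || is.null(names(len)) || any(!nzchar(names(len))))
            msg <- c(msg, sprintf("chromosomes of '%s' must be named", org))
        if (any(!is.finite(len)) || any(len <= 0))
            msg <- c(msg, sprintf("all chromosome lengths of '%s' must be > 0", org))
    }
    if (!all(orgs %in% names(object@prefixes)))
        msg <- c(msg, "prefixes must be named by organism label")
    if (anyDuplicated(object@prefixes[orgs]))
        msg <- c(msg, "organism prefixes must be distinct")
    if (length(msg)) msg else TRUE
})

#' Genome-wide fragment coverage track
#'
#' Per-base fragment pileup for one sample on one organism, together with
#' the mapped-fragment count used for density normalization.
#'
#' @slot cov an [IRanges::RleList], one run-length-encoded coverage vector
#'   per chromosome (units: fragments per bp).
#' @slot totalMapped number of fragments the track was built from.
#'
#' @seealso [computeCoverage()], [metageneProfile()].
#' @exportClass CoverageTrack
setClass("CoverageTrack",
    representation(cov = "RleList", totalMapped = "integer")
)

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (length(object@totalMapped) != 1L || is.na(object@totalMapped) ||
        object@totalMapped < 0L)
        msg <- c(msg, "totalMapped must be a single non-negative integer")
    if (any(vapply(object@cov, function(x) any(runValue(x) < 0), logical(1))))
        msg <- c(msg, "coverage must be non-negative everywhere")
    if (length(msg)) msg else TRUE
})

#' Per-sample spike-in normalization factors
#'
#' Read bookkeeping for ChIP-Rx normalization: deduplicated fragment counts
#' per organism and the resulting scale factor alpha = C / n_spike applied
#' to primary-organism peak counts.
#'
#' @slot table data.frame with columns \code{sample_id}, \code{n_primary},
#'   \code{n_spike}, \code{C}, \code{alpha}.
#'
#' @seealso [spikeInFactors()], [normalizationFactor()].
#' @exportClass SpikeInFactors
setClass("SpikeInFactors", representation(table = "data.frame"))

setValidity("SpikeInFactors", function(object) {
    tab <- object@table
    need <- c("sample_id", "n_primary", "n_spike", "C", "alpha")
    if (!all(need %in% colnames(tab)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (any(tab$n_primary < 0)) msg <- c(msg, "n_primary must be >= 0")
    if (any(tab$n_spike <= 0)) msg <- c(msg, "n_spike must be > 0")
    if (any(tab$alpha <= 0)) msg <- c(msg, "alpha must be > 0")
    if (anyDuplicated(tab$sample_id)) msg <- c(msg, "duplicate sample_id")
    if (length(msg)) msg else TRUE
})

#' Expression-stratified metagene profile
#'
#' Mean normalized density (reads per kilobase per 10 million mapped reads)
#' over a fixed flank--body--flank bin grid, one row per expression tier.
#' Bin 0 is always the 5'-most upstream bin regardless of gene strand.
#'
#' @slot values numeric matrix, tiers x (3 * bins).
#' @slot bins number of bins per segment (upstream flank, gene body,
#'   downstream flank).
#' @slot flank flank width in bp.
#' @slot nGenes named integer, genes averaged per tier.
#'
#' @seealso [metageneProfile()].
#' @exportClass MetageneProfile
setClass("MetageneProfile",
    representation(values = "matrix", bins = "integer", flank = "integer",
        nGenes = "integer")
)

setValidity("MetageneProfile", function(object) {
    msg <- character()
    if (ncol(object@values) != 3L * object@bins)
        msg <- c(msg, "values must have 3 * bins columns")
    if (any(object@values < 0)) msg <- c(msg, "profile values must be >= 0")
    if (nrow(object@values) != length(object@nGenes))
        msg <- c(msg, "one nGenes entry per tier row required")
    if (length(msg)) msg else TRUE
})
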