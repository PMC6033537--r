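#' Construct a two-organism genome layout
#'
#' @param primary,spikein organism labels (e.g. \code{"hs"}, \code{"dm"}).
#' @param chromLengths named list with one element per organism label, each
#'   a named numeric vector of chromosome lengths in bp.
#' @param prefixes named character vector mapping organism label to the
#'   chromosome-name prefix used in the combined namespace. Defaults to
#'   \code{label + "_"}.
#' @return a [GenomeLayout-class] object.
#' @examples
#' GenomeLayout("hs", "dm",
#'   chromLengths = list(hs = c(chr1 = 2e6), dm = c(chr2L = 5e5)))
#' @export
GenomeLayout <- function(primary, spikein, chromLengths,
                         prefixes = setNames(paste0(c(primary, spikein), "_"),
                                             c(primary, spikein))) {
    new("GenomeLayout", primary = primary, spikein = spikein,
        chromLengths = chromLengths, prefixes = prefixes)
}

#' @describeIn GenomeLayout label of the primary organism.
#' @param x a \code{GenomeLayout}.
#' @export
primaryOrganism <- function(x) x@primary

#' @describeIn GenomeLayout label of the spike-in organism.
#' @export
spikeinOrganism <- function(x) x@spikein

#' Chromosome lengths of one organism
#'
#' @param x a [GenomeLayout-class].
#' @param organism organism label; defaults to the primary organism.
#' @return named numeric vector of lengths in bp (native chromosome names).
#' @export
chromLengths <- function(x, organism = primaryOrganism(x)) {
    if (!organism %in% names(x@chromLengths))
        stop("unknown organism: ", organism)
    x@chromLengths[[organism]]
}

#' Seqlengths of the combined (prefixed) namespace
#'
#' @param x a [GenomeLayout-class].
#' @return named numeric vector covering both organisms, names prefixed.
#' @export
combinedSeqlengths <- function(x) {
    out <- numeric(0)
    for (org in c(x@primary, x@spikein)) {
        len <- x@chromLengths[[org]]
        out <- c(out, setNames(len, paste0(x@prefixes[[org]], names(len))))
    }
    out
}

#' Resolve combined chromosome names to organisms
#'
#' @param x a [GenomeLayout-class].
#' @param chroms character vector of combined-namespace chromosome names.
#' @return character vector of organism labels, same length as
#'   \code{chroms}. Unresolvable or ambiguous names are a hard error naming
#'   the offending chromosome.
#' @export
organismOf <- function(x, chroms) {
    chroms <- as.character(chroms)
    orgs <- c(x@primary, x@spikein)
    hit <- vapply(chroms, function(ch) {
        m <- orgs[startsWith(ch, x@prefixes[orgs])]
        ok <- vapply(m, function(o) {
            native <- substring(ch, nchar(x@prefixes[[o]]) + 1L)
            native %in% names(x@chromLengths[[o]])
        }, logical(1))
        m <- m[ok]
        if (length(m) == 0L)
            stop("chromosome '", ch, "' does not resolve to any organism",
                 call. = FALSE)
        if (length(m) > 1L)
            stop("chromosome '", ch, "' is ambiguous between organisms ",
                 paste(m, collapse = ", "), call. = FALSE)
        m
    }, character(1))
    unname(hit)
}

setMethod("show", "GenomeLayout", function(object) {
    cat("GenomeLayout\n")
    for (org in c(object@primary, object@spikein)) {
        role <- if (org == object@primary) "primary" else "spikein"
        len <- object@chromLengths[[org]]
        cat(sprintf("  %s (%s): %d chromosome(s), %.3g bp, prefix '%s'\n",
                    org, role, length(len), sum(len), object@prefixes[[org]]))
    }
})

#' Split combined-genome fragments by organism
#'
#' Assigns each aligned fragment to the organism its (prefixed) chromosome
#' name resolves to, and rewrites chromosome names to the organism's native
#' namespace (prefix stripped), as done when a combined-reference alignment
#' is partitioned into per-organism fragment sets.
#'
#' @param fragments a [GenomicRanges::GRanges] of aligned fragments on the
#'   combined namespace.
#' @param layout a [GenomeLayout-class].
#' @return named list of \code{GRanges} (one per organism, primary first);
#'   every input fragment lands in exactly one bucket, input order is
#'   preserved within buckets, and seqlengths are set from the layout.
#' @examples
#' lay <- GenomeLayout("hs", "dm",
#'   chromLengths = list(hs = c(chr1 = 1e4), dm = c(chr2L = 5e3)))
#' fr <- GenomicRanges::GRanges(c("hs_chr1", "dm_chr2L"),
#'   IRanges::IRanges(c(1, 11), width = 10))
#' lengths(splitByOrganism(fr, lay))
#' @export
splitByOrganism <- function(fragments, layout) {
    lev <- seqlevels(fragments)
    levOrg <- if (length(lev)) organismOf(layout, lev) else character(0)
    fragOrg <- levOrg[match(as.character(seqnames(fragments)), lev)]
    out <- list()
    for (org in c(layout@primary, layout@spikein)) {
        gr <- fragments[fragOrg == org]
        keep <- lev[levOrg == org]
        gr <- keepSeqlevels(gr, keep, pruning.mode = "coarse")
        native <- substring(seqlevels(gr), nchar(layout@prefixes[[org]]) + 1L)
        seqlevels(gr) <- native
        seqlengths(gr) <- layout@chromLengths[[org]][native]
        out[[org]] <- gr
    }
    out
}

#' Remove duplicate fragments
#'
#' Coordinate-identity deduplication: at most one fragment is retained per
#' (chromosome, start, end, strand) tuple, keeping the first occurrence.
#' A simplified stand-in for PCR-duplicate removal on one sample.
#'
#' @param fragments a \code{GRanges}.
#' @return subset of \code{fragments} with duplicates removed.
#' @export
deduplicateFragments <- function(fragments) {
    if (length(fragments) == 0L) return(fragments)
    key <- paste(as.character(seqnames(fragments)), start(fragments),
                 end(fragments), as.character(strand(fragments)), sep = "\r")
    fragments[!duplicated(key)]
}

#' Spike-in normalization factor
#'
#' \code{alpha = C / n_spike}: the per-sample scale that puts primary-genome
#' peak counts on a common footing across samples, using the spike-in
#' fragment count as the yardstick (reads-per-million-spike-in for the
#' default \code{C = 1e6}).
#'
#' @param nSpike deduplicated spike-in fragment count (> 0).
#' @param C scale constant (> 0), default \code{1e6}.
#' @return the normalization factor alpha.
#' @examples
#' normalizationFactor(1e6)      # 1
#' normalizationFactor(2e6)      # 0.5
#' @export
normalizationFactor <- function(nSpike, C = 1e6) {
    if (any(C <= 0)) stop("C must be > 0")
    if (any(nSpike <= 0)) stop("no spike-in reads: n_spike must be > 0")
    C / nSpike
}

#' Compute per-sample spike-in factors
#'
#' Splits each sample's combined-genome fragments by organism, deduplicates
#' per organism, counts fragments, and derives alpha = C / n_spike.
#' A warning is emitted when the estimated spike fraction falls outside the
#' usual working range (0.5\%--10\%), which typically signals a mixing or
#' annotation problem.
#'
#' @param fragments a \code{GRanges} (one sample) or a named list of
#'   \code{GRanges} (one element per sample).
#' @param layout a [GenomeLayout-class].
#' @param C scale constant, default \code{1e6}.
#' @param sampleId sample name used when \code{fragments} is a single
#'   \code{GRanges}.
#' @param dedup deduplicate before counting (default \code{TRUE}).
#' @return a [SpikeInFactors-class] object.
#' @export
spikeInFactors <- function(fragments, layout, C = 1e6,
                           sampleId = "sample", dedup = TRUE) {
    if (is(fragments, "GRanges"))
        fragments <- setNames(list(fragments), sampleId)
    rows <- lapply(names(fragments), function(id) {
        buckets <- splitByOrganism(fragments[[id]], layout)
        if (dedup) buckets <- lapply(buckets, deduplicateFragments)
        nP <- length(buckets[[primaryOrganism(layout)]])
        nS <- length(buckets[[spikeinOrganism(layout)]])
        if (nS == 0L)
            stop("no spike-in reads in sample '", id, "'")
        data.frame(sample_id = id, n_primary = nP, n_spike = nS, C = C,
                   alpha = normalizationFactor(nS, C),
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    frac <- tab$n_spike / (tab$n_spike + tab$n_primary)
    off <- frac < 0.005 | frac > 0.10
    if (any(off))
        warning("estimated spike fraction outside [0.005, 0.10] for sample(s): ",
                paste(tab$sample_id[off], collapse = ", "))
    new("SpikeInFactors", table = tab)
}

#' @describeIn spikeInFactors normalization factors as a named vector.
#' @param x a \code{SpikeInFactors}.
#' @export
alpha <- function(x) setNames(x@table$alpha, x@table$sample_id)

#' @describeIn spikeInFactors estimated spike fractions
#'   n_spike / (n_spike + n_primary) as a named vector.
#' @export
spikeFraction <- function(x)
    setNames(x@table$n_spike / (x@table$n_spike + x@table$n_primary),
             x@table$sample_id)

#' @describeIn spikeInFactors the underlying per-sample table.
#' @export
factorTable <- function(x) x@table

setMethod("show", "SpikeInFactors", function(object) {
    cat("SpikeInFactors for", nrow(object@table), "sample(s)\n")
    print(object@table, row.names = FALSE)
})

#' Spike-in-normalized peak signal
#'
#' Counts primary-organism fragments overlapping each peak by at least one
#' base and scales the count by the sample's normalization factor.
#'
#' @param peaks \code{GRanges} of peaks on the primary organism (native
#'   chromosome names).
#' @param fragments deduplicated primary-organism fragment \code{GRanges}.
#' @param alpha the sample's normalization factor.
#' @param layout optional [GenomeLayout-class]; when supplied, peak
#'   chromosomes absent from the primary organism are a hard error.
#' @return \code{peaks} with metadata columns \code{count} and
#'   \code{signal} (= count x alpha) added.
#' @export
normalizePeakCounts <- function(peaks, fragments, alpha, layout = NULL) {
    if (!is.null(layout)) {
        known <- names(chromLengths(layout, primaryOrganism(layout)))
        bad <- setdiff(as.character(unique(seqnames(peaks))), known)
        if (length(bad))
            stop("peak chromosome(s) absent from layout: ",
                 paste(bad, collapse = ", "))
    }
    cnt <- countOverlaps(peaks, fragments, ignore.strand = TRUE)
    mcols(peaks)$count <- cnt
    mcols(peaks)$signal <- cnt * alpha
    peaks
}
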