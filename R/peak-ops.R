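#' Call broad enrichment domains against a control track
#'
#' Plumbing caller for end-to-end synthetic runs: slides fixed windows
#' across the genome, tests each window's fragment count against a Poisson
#' upper tail whose mean is the depth-scaled control count (floored at the
#' genome-wide expected rate), and merges retained windows that overlap or
#' lie within \code{mergeGap} bp into domains. It deliberately does not
#' reproduce a production peak caller's model.
#'
#' @param sampleCov,controlCov [CoverageTrack-class] objects on the same
#'   chromosomes; \code{controlCov} may be \code{NULL}, in which case the
#'   genome-wide uniform rate is the null mean everywhere.
#' @param windowBp,stepBp window width and step in bp (defaults 200/100).
#' @param pCutoff Poisson upper-tail cutoff, default \code{1e-5}.
#' @param mergeGap maximum gap between retained windows that is still
#'   merged, default 500 bp.
#' @return sorted, non-overlapping domain \code{GRanges} named
#'   \code{peak_1..n}. A zero-depth sample yields an empty set with a
#'   warning.
#' @export
callEnrichmentDomains <- function(sampleCov, controlCov = NULL,
                                  windowBp = 200L, stepBp = 100L,
                                  pCutoff = 1e-5, mergeGap = 500L) {
    Ns <- totalMapped(sampleCov)
    if (Ns == 0L) {
        warning("zero-depth sample: no domains called")
        return(GRanges())
    }
    covS <- coverageRle(sampleCov)
    mass <- function(r) sum(as.numeric(runValue(r)) * runLength(r))
    fragLenS <- sum(vapply(covS, mass, numeric(1))) / Ns
    genomeLen <- sum(vapply(covS, length, numeric(1)))
    globalRate <- Ns * windowBp / genomeLen
    if (!is.null(controlCov)) {
        Nc <- totalMapped(controlCov)
        covC <- coverageRle(controlCov)
        fragLenC <- if (Nc > 0) sum(vapply(covC, mass, numeric(1))) / Nc else 1
    }
    hits <- list()
    for (ch in names(covS)) {
        len <- length(covS[[ch]])
        if (len < windowBp) next
        starts <- seq.int(1L, len - windowBp + 1L, by = stepBp)
        cntS <- round(viewSums(Views(covS[[ch]], start = starts,
                                     width = windowBp)) / fragLenS)
        lam <- rep(globalRate, length(starts))
        if (!is.null(controlCov) && totalMapped(controlCov) > 0 &&
            ch %in% names(covC)) {
            cntC <- viewSums(Views(covC[[ch]], start = starts,
                                   width = windowBp)) / fragLenC
            lam <- pmax(cntC * Ns / totalMapped(controlCov), globalRate)
        }
        keep <- ppois(cntS - 1, lam, lower.tail = FALSE) <= pCutoff
        if (any(keep)) {
            h <- GRanges(ch, IRanges(starts[keep], width = windowBp))
            seqlevels(h) <- names(covS)
            hits[[ch]] <- h
        }
    }
    if (length(hits) == 0L) return(GRanges())
    dom <- reduce(sort(do.call(c, unname(hits))),
                  min.gapwidth = mergeGap + 1L)
    names(dom) <- paste0("peak_", seq_along(dom))
    dom
}

#' Classify peaks across a control and two condition clones
#'
#' Builds the cross-condition peak universe and labels every peak:
#' condition peaks present in both clones (>= 1 bp overlap, anchored on the
#' clone-1 interval) are \code{common} when they also overlap a control
#' peak and \code{unique_condition} otherwise; control peaks overlapping
#' neither clone are \code{unique_control} (overlap with either clone makes
#' them \code{common}); clone peaks with no mate in the other clone are
#' \code{unreplicated} and are excluded from downstream analyses.
#'
#' @param control,clone1,clone2 peak \code{GRanges} on the same genome.
#' @return \code{GRanges} with metadata columns \code{label} (factor) and
#'   \code{origin} (\code{"clone1"}, \code{"clone2"} or \code{"control"}).
#' @export
classifyPeaks <- function(control, clone1, clone2) {
    labLevels <- c("common", "unique_condition", "unique_control",
                   "unreplicated")
    r1 <- overlapsAny(clone1, clone2, ignore.strand = TRUE)
    repl <- clone1[r1]
    replLab <- ifelse(overlapsAny(repl, control, ignore.strand = TRUE),
                      "common", "unique_condition")
    un1 <- clone1[!r1]
    un2 <- clone2[!overlapsAny(clone2, clone1, ignore.strand = TRUE)]
    ctrlLab <- ifelse(overlapsAny(control, clone1, ignore.strand = TRUE) |
                      overlapsAny(control, clone2, ignore.strand = TRUE),
                      "common", "unique_control")
    strip <- function(gr) {
        gr <- granges(gr)
        names(gr) <- NULL
        gr
    }
    out <- c(strip(repl), strip(un1), strip(un2), strip(control))
    mcols(out)$label <- factor(
        c(replLab, rep("unreplicated", length(un1) + length(un2)), ctrlLab),
        levels = labLevels)
    mcols(out)$origin <- c(rep("clone1", length(repl) + length(un1)),
                           rep("clone2", length(un2)),
                           rep("control", length(control)))
    out
}

#' Promoter windows around TSSs
#'
#' Strand-aware promoter intervals (default 2 kb upstream to 500 bp
#' downstream of the TSS), trimmed to chromosome bounds when seqlengths
#' are available.
#'
#' @param genes \code{GRanges} gene models with names and strand.
#' @param upstream,downstream window extent in bp relative to the TSS.
#' @return named promoter \code{GRanges}.
#' @export
promoterWindows <- function(genes, upstream = 2000L, downstream = 500L) {
    if (upstream + downstream <= 0) stop("promoter window must be non-empty")
    p <- promoters(genes, upstream = upstream, downstream = downstream)
    p <- trim(p)
    start(p) <- pmax(start(p), 1L)
    p
}

#' Genes whose promoters carry a peak
#'
#' @param peaks peak \code{GRanges}.
#' @param promoters named promoter \code{GRanges} (see [promoterWindows()]).
#' @return sorted character vector of gene ids with >= 1 bp peak overlap.
#' @export
assignPromoters <- function(peaks, promoters) {
    if (is.null(names(promoters))) stop("promoters must be named by gene id")
    sort(unique(names(promoters)[overlapsAny(promoters, peaks,
                                             ignore.strand = TRUE)]))
}

#' Venn region counts for named sets
#'
#' Counts every region of the inclusion--exclusion partition of the given
#' sets; region counts sum to the size of the union.
#'
#' @param sets named list (>= 2 elements, unique names) of id vectors.
#' @return data.frame with one logical membership column per set plus
#'   \code{count}, covering all \code{2^n - 1} non-outside regions.
#' @export
vennCounts <- function(sets) {
    if (length(sets) < 2L) stop("need at least 2 sets")
    nm <- names(sets)
    if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
        stop("sets must have unique non-empty names")
    sets <- lapply(sets, unique)
    elems <- unique(unlist(sets, use.names = FALSE))
    member <- vapply(sets, function(s) elems %in% s, logical(length(elems)))
    if (length(elems) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, nm))
    combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-2^length(sets), , drop = FALSE]
    colnames(combos) <- nm
    combos <- combos[do.call(order, as.data.frame(-combos)), , drop = FALSE]
    rownames(combos) <- NULL
    key <- apply(member, 1L, paste, collapse = ".")
    ckey <- apply(combos, 1L, paste, collapse = ".")
    combos$count <- as.integer(table(factor(key, levels = ckey)))
    combos
}

#' Reference-anchored peak-promoter set construction
#'
#' Combines two reference promoter sets with a sample's own set the way a
#' pre-tumor ("tumor-initiating") PRC2 target list is assembled: promoters
#' shared by both references, plus promoters unique to the sample (absent
#' from either reference).
#'
#' @param refA,refB,sample character vectors of gene ids (promoter-level
#'   sets, e.g. from [assignPromoters()]).
#' @return sorted character vector:
#'   \code{(refA intersect refB) union (sample minus (refA union refB))}.
#' @examples
#' buildInitiatingSet(c("P1","P2","P3"), c("P2","P3","P4"), c("P3","P5"))
#' @export
buildInitiatingSet <- function(refA, refB, sample) {
    sort(unique(c(intersect(refA, refB),
                  setdiff(sample, union(refA, refB)))))
}
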