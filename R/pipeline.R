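## split + dedup the named samples down to primary-organism fragments
.primaryFragments <- function(dataset, sampleNames) {
    layout <- dataset$genome$layout
    out <- lapply(sampleNames, function(nm) {
        if (!nm %in% names(dataset$samples))
            stop("sample '", nm, "' not in dataset")
        deduplicateFragments(
            splitByOrganism(dataset$samples[[nm]],
                            layout)[[primaryOrganism(layout)]])
    })
    setNames(out, sampleNames)
}

.testToList <- function(tt) list(t = tt$statistic, df = tt$df,
                                 p = tt$p.value, method = tt$method)

## retention chain: spike-in factors -> per-peak ratios ->
## median split -> cross-mark comparison -> fraction increased -> venn
.retentionWorkflow <- function(dataset, promoterUpstream, promoterDownstream,
                               C) {
    layout <- dataset$genome$layout
    need <- c("H3K27me3_control", "H3K27me3_clone1", "H3K27me3_clone2")
    factors <- spikeInFactors(dataset$samples[need], layout, C = C)
    prim <- .primaryFragments(dataset, need)
    inputCov <- if ("input_control" %in% names(dataset$samples))
        computeCoverage(.primaryFragments(dataset, "input_control")[[1L]],
                        layout) else NULL
    covs <- lapply(prim, computeCoverage, seqlen = layout)
    ## 1-kb windows suit the domain-scale marks these workflows analyse
    call <- function(cov) callEnrichmentDomains(cov, inputCov,
                                                windowBp = 1000L,
                                                stepBp = 500L)
    dom1 <- call(covs$H3K27me3_clone1)
    dom2 <- call(covs$H3K27me3_clone2)
    domC <- call(covs$H3K27me3_control)
    universe <- dom1[overlapsAny(dom1, dom2, ignore.strand = TRUE)]
    if (length(universe) < 4L)
        stop("retention workflow: replicated peak universe too small")
    names(universe) <- paste0("peak_", seq_along(universe))
    al <- alpha(factors)
    sig <- vapply(need, function(nm)
        mcols(normalizePeakCounts(universe, prim[[nm]], al[[nm]]))$signal,
        numeric(length(universe)))
    rownames(sig) <- names(universe)
    pr <- perPeakRatio(sig[, c("H3K27me3_clone1", "H3K27me3_clone2")],
                       sig[, "H3K27me3_control"])
    ## depth normalization of the same counts, to expose the masking
    tab <- factorTable(factors)
    alDepth <- setNames(1e6 / tab$n_primary, tab$sample_id)
    sigD <- sweep(sweep(sig, 2L, al[colnames(sig)], "/"), 2L,
                  alDepth[colnames(sig)], "*")
    prD <- perPeakRatio(sigD[, c("H3K27me3_clone1", "H3K27me3_clone2")],
                        sigD[, "H3K27me3_control"])
    groups <- medianSplit(pr$ratios)
    k27mName <- intersect(c("H3.3K27M_clone1", "H3.3K27M_clone2"),
                          names(dataset$samples))[1L]
    k27m <- NULL
    if (!is.na(k27mName)) {
        k27mPrim <- .primaryFragments(dataset, k27mName)[[1L]]
        k27mFac <- spikeInFactors(dataset$samples[[k27mName]], layout,
                                  C = C, sampleId = k27mName)
        k27mSig <- mcols(normalizePeakCounts(universe, k27mPrim,
                                             alpha(k27mFac)[[1L]]))$signal
        names(k27mSig) <- names(universe)
        k27m <- groupDensityCompare(groups, k27mSig)
    }
    ctrlDens <- setNames(sig[, "H3K27me3_control"], names(universe))
    ctrlCompare <- groupDensityCompare(groups, ctrlDens)
    ## promoter-level sets and the reference-anchored construction
    prom <- promoterWindows(dataset$genome$genes, promoterUpstream,
                            promoterDownstream)
    promSets <- list(control = assignPromoters(domC, prom),
                     clone1 = assignPromoters(dom1, prom),
                     clone2 = assignPromoters(dom2, prom))
    venn <- vennCounts(promSets)
    truthProm <- assignPromoters(
        dataset$truth$domains$H3K27me3[
            mcols(dataset$truth$domains$H3K27me3)$present_control], prom)
    initiating <- buildInitiatingSet(promSets$control, truthProm,
                                     promSets$clone1)
    ret <- mcols(dataset$truth$domains$H3K27me3)$role == "retained_promoter"
    retainedTruth <- dataset$truth$domains$H3K27me3[ret]
    leastRetainedFrac <- if (length(retainedTruth))
        mean(overlapsAny(universe[groups$least_reduced], retainedTruth,
                         ignore.strand = TRUE))
        else NA_real_
    mostRetainedFrac <- if (length(retainedTruth))
        mean(overlapsAny(universe[groups$most_reduced], retainedTruth,
                         ignore.strand = TRUE))
        else NA_real_
    list(
        workflow = "retention",
        n_universe = length(universe),
        factors = factorTable(factors),
        median_spikein_ratio = unname(median(pr$ratios)),
        median_depth_ratio = unname(median(prD$ratios)),
        n_excluded_zero_control = length(pr$excluded),
        fraction_increased_pct = fractionIncreased(pr$ratios),
        group_sizes = lengths(groups),
        k27m_compare = if (!is.null(k27m))
            list(summary = k27m$summary, test = .testToList(k27m$test)),
        control_density_compare = list(summary = ctrlCompare$summary,
                                       test = .testToList(ctrlCompare$test)),
        venn = venn,
        n_shared_promoters = venn$count[venn$control & venn$clone1 &
                                        venn$clone2],
        n_initiating = length(initiating),
        planted = list(
            f_bulk = unname(dataset$config$reduction[["H3K27me3"]]),
            f_retained = dataset$config$retainedReduction,
            retained_frac_in_least_reduced = leastRetainedFrac,
            retained_frac_in_most_reduced = mostRetainedFrac))
}

## redistribution chain: classify across conditions -> binary annotation
## -> Jaccard clustering -> cross-mark comparisons
.redistributionWorkflow <- function(dataset, promoterUpstream,
                                    promoterDownstream, C, k) {
    layout <- dataset$genome$layout
    need <- c("Ezh2_control", "Ezh2_clone1", "Ezh2_clone2")
    prim <- .primaryFragments(dataset, need)
    inputCov <- if ("input_control" %in% names(dataset$samples))
        computeCoverage(.primaryFragments(dataset, "input_control")[[1L]],
                        layout) else NULL
    covs <- lapply(prim, computeCoverage, seqlen = layout)
    call <- function(cov) callEnrichmentDomains(cov, inputCov,
                                                windowBp = 1000L,
                                                stepBp = 500L)
    domC <- call(covs$Ezh2_control)
    dom1 <- call(covs$Ezh2_clone1)
    dom2 <- call(covs$Ezh2_clone2)
    classification <- classifyPeaks(domC, dom1, dom2)
    peaks <- classification[mcols(classification)$label %in%
                            c("common", "unique_condition") &
                            mcols(classification)$origin == "clone1"]
    names(peaks) <- paste0("peak_", seq_along(peaks))
    if (length(peaks) < max(4L, k))
        stop("redistribution workflow: too few replicated condition peaks")
    prom <- promoterWindows(dataset$genome$genes, promoterUpstream,
                            promoterDownstream)
    k27me3Feat <- if ("H3K27me3_control" %in% names(dataset$samples))
        call(computeCoverage(.primaryFragments(dataset,
            "H3K27me3_control")[[1L]], layout))
        else dataset$truth$domains$H3K27me3
    k27mName <- intersect(c("H3.3K27M_clone1", "H3.3K27M_clone2"),
                          names(dataset$samples))[1L]
    if (is.na(k27mName))
        stop("redistribution workflow needs an H3.3K27M sample")
    k27mPrim <- .primaryFragments(dataset, k27mName)[[1L]]
    k27mFeat <- call(computeCoverage(k27mPrim, layout))
    features <- list(promoter = prom, H3K4me1 = dataset$truth$domains$H3K4me1,
                     H3K27me3 = k27me3Feat, H3.3K27M = k27mFeat)
    mat <- annotatePeaks(peaks, features)
    kUse <- min(k, nrow(unique(mat)))
    assignment <- clusterBinary(mat, k = kUse)
    ord <- heatmapOrder(mat, assignment)
    lab <- mcols(peaks)$label
    groups <- list(unique_condition = names(peaks)[lab == "unique_condition"],
                   common = names(peaks)[lab == "common"])
    k27mFac <- spikeInFactors(dataset$samples[[k27mName]], layout, C = C,
                              sampleId = k27mName)
    k27mSig <- mcols(normalizePeakCounts(peaks, k27mPrim,
                                         alpha(k27mFac)[[1L]]))$signal
    names(k27mSig) <- names(peaks)
    k27mCompare <- groupDensityCompare(groups, k27mSig)
    poised <- dataset$truth$regions$poised_enhancers
    poisedInd <- setNames(as.numeric(overlapsAny(peaks, poised,
                                                 ignore.strand = TRUE)),
                          names(peaks))
    poisedCompare <- groupDensityCompare(groups, poisedInd)
    purity <- vapply(split(names(assignment), assignment), function(ids)
        mean(poisedInd[ids]), numeric(1))
    labCounts <- table(mcols(classification)$label)
    list(
        workflow = "redistribution",
        n_peaks = length(peaks),
        classification_counts = as.list(labCounts),
        k_used = kUse,
        cluster_sizes = as.list(table(assignment)),
        heatmap_order_head = utils::head(ord, 10L),
        k27m_compare = list(summary = k27mCompare$summary,
                            test = .testToList(k27mCompare$test)),
        poised_enrichment = list(
            frac_unique_on_poised = unname(mean(poisedInd[groups$unique_condition])),
            frac_common_on_poised = unname(mean(poisedInd[groups$common])),
            test = .testToList(poisedCompare$test)),
        max_cluster_poised_purity = unname(max(purity)))
}

#' Run a complete analysis workflow
#'
#' \code{"retention"} runs the locus-specific H3K27me3 retention chain:
#' spike-in factors, replicated peak universe, per-peak
#' condition-vs-control ratios under spike-in and under per-sample depth
#' normalization, most/least-reduced median split, H3.3K27M density
#' comparison between the groups, fraction of increased peaks, promoter
#' Venn counts, and the reference-anchored initiating promoter set.
#' \code{"redistribution"} runs the Ezh2 redistribution chain: peak
#' classification across control and two condition clones, binary feature
#' annotation, Jaccard/average-linkage clustering into \code{k} classes,
#' and common-vs-condition-unique comparisons of H3.3K27M density and
#' poised-enhancer overlap.
#'
#' Given the same dataset (or the same configuration, which regenerates an
#' identical dataset) the report and the written JSON are byte-identical
#' across runs.
#'
#' @param x a dataset from [simulateDataset()] (or a [simulationConfig()],
#'   which is simulated first).
#' @param workflow \code{"retention"} or \code{"redistribution"}.
#' @param outDir optional output directory: writes \code{report_<wf>.json},
#'   tables, and (for redistribution) the annotation heatmap PNG.
#' @param k cluster count for the redistribution chain.
#' @param promoterUpstream,promoterDownstream promoter window around the
#'   TSS in bp.
#' @param C spike-in normalization constant.
#' @return the report, a named list of computed statistics.
#' @export
runPipeline <- function(x, workflow = c("retention", "redistribution"),
                        outDir = NULL, k = 5L, promoterUpstream = 2000L,
                        promoterDownstream = 500L, C = 1e6) {
    workflow <- match.arg(workflow)
    dataset <- if (inherits(x, "SimulationConfig")) simulateDataset(x) else x
    report <- if (workflow == "retention")
        .retentionWorkflow(dataset, promoterUpstream, promoterDownstream, C)
    else
        .redistributionWorkflow(dataset, promoterUpstream,
                                promoterDownstream, C, k)
    report$seed <- dataset$config$seed
    report$config_hash <- configHash(dataset$config)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(report,
            file.path(outDir, paste0("report_", workflow, ".json")),
            auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    }
    report
}
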