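#' Read a BED file
#'
#' Accepts BED3--BED6 and broadPeak-style files (columns beyond 6 are
#' ignored). Comment, \code{track} and \code{browser} lines are skipped.
#' BED coordinates are 0-based half-open and are converted to the 1-based
#' closed convention of \code{GRanges}; a malformed line is a hard error
#' reporting its line number.
#'
#' @param path file path.
#' @return a \code{GRanges}; column 4 becomes \code{names()}, column 5 a
#'   \code{score} column, column 6 the strand.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lineNo <- seq_along(lines)
    skip <- grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
    lines <- lines[!skip]; lineNo <- lineNo[!skip]
    if (length(lines) == 0L) return(GRanges())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("malformed BED line ", lineNo[which(nf < 3L)[1L]],
             ": fewer than 3 fields")
    chrom <- vapply(parts, `[[`, character(1), 1L)
    startTxt <- vapply(parts, `[[`, character(1), 2L)
    endTxt <- vapply(parts, `[[`, character(1), 3L)
    start0 <- suppressWarnings(as.numeric(startTxt))
    end0 <- suppressWarnings(as.numeric(endTxt))
    bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
    if (length(bad))
        stop("malformed BED line ", lineNo[bad[1L]],
             ": non-integer coordinates")
    bad <- which(start0 < 0 | start0 >= end0)
    if (length(bad))
        stop("malformed BED line ", lineNo[bad[1L]],
             ": requires 0 <= start < end")
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    if (all(nf >= 4L)) names(gr) <- vapply(parts, `[[`, character(1), 4L)
    if (all(nf >= 5L))
        mcols(gr)$score <- suppressWarnings(
            as.numeric(vapply(parts, `[[`, character(1), 5L)))
    if (all(nf >= 6L)) {
        str <- vapply(parts, `[[`, character(1), 6L)
        bad <- which(!str %in% c("+", "-", "."))
        if (length(bad))
            stop("malformed BED line ", lineNo[bad[1L]], ": bad strand '",
                 str[bad[1L]], "'")
        strand(gr) <- sub(".", "*", str, fixed = TRUE)
    }
    gr
}

#' Write intervals as BED6
#'
#' 1-based closed \code{GRanges} coordinates are written 0-based half-open.
#'
#' @param gr a \code{GRanges}; \code{names(gr)} fills the name column
#'   (\code{"."} when absent), a \code{score} column fills column 5.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
    nm <- if (is.null(names(gr))) rep(".", length(gr)) else names(gr)
    sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else
        rep(0L, length(gr))
    str <- sub("*", ".", as.character(strand(gr)), fixed = TRUE)
    df <- data.frame(as.character(seqnames(gr)),
                     format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
                     format(end(gr), scientific = FALSE, trim = TRUE),
                     nm, sc, str)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read/write a genome layout as YAML
#'
#' The YAML schema mirrors [GenomeLayout()]: per-organism role
#' (primary/spikein), prefix, and chromosome lengths.
#'
#' @param path YAML file path.
#' @return [readGenomeLayout()]: a [GenomeLayout-class].
#' @export
readGenomeLayout <- function(path) {
    y <- yaml::read_yaml(path)
    GenomeLayout(
        primary = y$primary$label, spikein = y$spikein$label,
        chromLengths = setNames(
            list(unlist(y$primary$chromosomes),
                 unlist(y$spikein$chromosomes)),
            c(y$primary$label, y$spikein$label)),
        prefixes = setNames(c(y$primary$prefix, y$spikein$prefix),
                            c(y$primary$label, y$spikein$label)))
}

#' @rdname readGenomeLayout
#' @param layout a [GenomeLayout-class] to serialize.
#' @export
writeGenomeLayout <- function(layout, path) {
    org <- function(o) list(label = o,
        prefix = unname(layout@prefixes[[o]]),
        chromosomes = as.list(layout@chromLengths[[o]]))
    yaml::write_yaml(list(primary = org(primaryOrganism(layout)),
                          spikein = org(spikeinOrganism(layout))), path)
    invisible(path)
}

#' Read/write gene models as TSV
#'
#' Five/six-column TSV: gene_id, chrom, start (0-based), end (exclusive),
#' strand, and optionally tier.
#'
#' @param path file path.
#' @return [readGeneModels()]: named \code{GRanges}, with a \code{tier}
#'   column when present in the file.
#' @export
readGeneModels <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand)
    names(gr) <- df$gene_id
    if ("tier" %in% colnames(df))
        mcols(gr)$tier <- factor(df$tier, levels = c("high", "medium", "low"))
    gr
}

#' @rdname readGeneModels
#' @param genes named gene-model \code{GRanges}.
#' @export
writeGeneModels <- function(genes, path) {
    df <- data.frame(gene_id = names(genes),
                     chrom = as.character(seqnames(genes)),
                     start = start(genes) - 1L, end = end(genes),
                     strand = as.character(strand(genes)),
                     stringsAsFactors = FALSE)
    if (!is.null(mcols(genes)$tier)) df$tier <- as.character(mcols(genes)$tier)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read/write a per-gene expression table (2-column TSV)
#'
#' @param path file path.
#' @return [readExpression()]: named numeric vector.
#' @export
readExpression <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    setNames(df[[2L]], df[[1L]])
}

#' @rdname readExpression
#' @param expression named numeric vector.
#' @export
writeExpression <- function(expression, path) {
    ## %.17g keeps doubles exact through the round trip
    write.table(data.frame(gene_id = names(expression),
                           expression = sprintf("%.17g", expression)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## 32-bit FNV-1a over the characters of a string, without integer overflow
.fnv1a32 <- function(txt) {
    bytes <- utf8ToInt(txt) %% 256L
    h <- 2166136261
    m <- 16777619
    for (b in bytes) {
        lo8 <- h %% 256
        h <- (h - lo8) + bitwXor(as.integer(lo8), as.integer(b))
        lo <- h %% 65536; hi <- (h - lo) / 65536
        h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 2^32
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a simulation configuration
#'
#' Stable 32-bit content hash of the JSON serialization; changes iff the
#' configuration changes.
#'
#' @param config a [simulationConfig()].
#' @return 8-hex-digit string.
#' @export
configHash <- function(config) {
    .fnv1a32(as.character(jsonlite::toJSON(unclass(config),
        auto_unbox = TRUE, digits = NA)))
}

#' Write a simulated dataset to disk
#'
#' Emits per-sample fragment BEDs, per-mark truth-domain BEDs plus full
#' truth tables (TSV), gene models and expression (TSV), the genome layout
#' (YAML), and a JSON manifest recording the seed and a configuration
#' hash.
#'
#' @param dataset output of [simulateDataset()].
#' @param dir output directory; an existing non-empty directory is an
#'   error unless \code{overwrite = TRUE}.
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest, invisibly.
#' @export
writeDataset <- function(dataset, dir, overwrite = FALSE) {
    if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
        stop("directory ", dir, " is not empty (use overwrite = TRUE)")
    dir.create(file.path(dir, "fragments"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    files <- list()
    for (nm in names(dataset$samples)) {
        f <- file.path("fragments", paste0(nm, ".bed"))
        writeBed(dataset$samples[[nm]], file.path(dir, f))
        files[[paste0("fragments_", nm)]] <- f
    }
    for (mk in names(dataset$truth$domains)) {
        dom <- dataset$truth$domains[[mk]]
        safe <- gsub("[^A-Za-z0-9]", "", mk)
        f <- file.path("truth", paste0(safe, "_domains.bed"))
        bed <- granges(dom)
        names(bed) <- if (length(dom)) mcols(dom)$role else NULL
        writeBed(bed, file.path(dir, f))
        ft <- file.path("truth", paste0(safe, "_domains.tsv"))
        df <- data.frame(name = names(dom),
                         chrom = as.character(seqnames(dom)),
                         start = start(dom) - 1L, end = end(dom),
                         as.data.frame(mcols(dom)),
                         stringsAsFactors = FALSE)
        write.table(df, file.path(dir, ft), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files[[paste0("truth_", safe)]] <- f
    }
    writeGeneModels(dataset$genome$genes, file.path(dir, "genes.tsv"))
    writeExpression(dataset$genome$expression,
                    file.path(dir, "expression.tsv"))
    writeGenomeLayout(dataset$genome$layout, file.path(dir, "layout.yaml"))
    files$genes <- "genes.tsv"; files$expression <- "expression.tsv"
    files$layout <- "layout.yaml"
    manifest <- list(seed = dataset$config$seed,
                     config_hash = configHash(dataset$config),
                     n_samples = length(dataset$samples),
                     depth = dataset$config$depth,
                     files = files)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}

#' Load a dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @return list with \code{layout}, \code{genes}, \code{expression},
#'   \code{samples} (fragment \code{GRanges} per sample) and \code{truth}
#'   (per-mark domain \code{GRanges}).
#' @export
loadDataset <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
    layout <- readGenomeLayout(file.path(dir, "layout.yaml"))
    genes <- readGeneModels(file.path(dir, "genes.tsv"))
    expression <- readExpression(file.path(dir, "expression.tsv"))
    fragFiles <- list.files(file.path(dir, "fragments"), pattern = "\\.bed$",
                            full.names = TRUE)
    samples <- lapply(fragFiles, function(f) {
        gr <- readBed(f)
        lens <- combinedSeqlengths(layout)
        seqlevels(gr) <- names(lens)
        seqlengths(gr) <- lens
        gr
    })
    names(samples) <- sub("\\.bed$", "", basename(fragFiles))
    truthFiles <- list.files(file.path(dir, "truth"), pattern = "\\.bed$",
                             full.names = TRUE)
    truth <- lapply(truthFiles, readBed)
    names(truth) <- sub("_domains\\.bed$", "", basename(truthFiles))
    list(layout = layout, genes = genes, expression = expression,
         samples = samples, truth = truth, manifest = manifest)
}

#' Export a coverage track as bedGraph
#'
#' One line per constant-coverage run, 0-based half-open coordinates;
#' zero-coverage runs are omitted.
#'
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    cov <- coverageRle(track)
    for (ch in names(cov)) {
        r <- cov[[ch]]
        ends <- cumsum(runLength(r))
        starts <- ends - runLength(r)
        val <- runValue(r)
        keep <- val != 0
        if (!any(keep)) next
        writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                           val[keep]), con)
    }
    invisible(path)
}

#' Write a metagene profile as TSV
#'
#' Tier x bin matrix with a leading \code{tier} column.
#'
#' @param profile a [MetageneProfile-class].
#' @param path output path.
#' @export
writeProfile <- function(profile, path) {
    m <- profileMatrix(profile)
    df <- data.frame(tier = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
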