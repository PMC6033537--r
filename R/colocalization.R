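#' Binary occupancy annotation of peaks against feature sets
#'
#' \code{cell(i, j) = 1} iff peak i overlaps any interval of feature j by
#' at least one base.
#'
#' @param peaks peak \code{GRanges}; row names come from \code{names(peaks)}
#'   (or \code{peak_1..n} when unnamed).
#' @param features named list of feature \code{GRanges} (unique names). An
#'   empty feature set is allowed and yields an all-zero column with a
#'   warning.
#' @return integer 0/1 matrix, peaks x features.
#' @export
annotatePeaks <- function(peaks, features) {
    nm <- names(features)
    if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
        stop("features must have unique non-empty names")
    empty <- vapply(features, length, integer(1)) == 0L
    if (any(empty))
        warning("empty feature set(s): ", paste(nm[empty], collapse = ", "))
    m <- vapply(features, function(f)
        as.integer(countOverlaps(peaks, f, ignore.strand = TRUE) > 0L),
        integer(length(peaks)))
    if (length(peaks) == 1L)
        m <- matrix(m, nrow = 1L, dimnames = list(NULL, nm))
    rownames(m) <- if (is.null(names(peaks)))
        paste0("peak_", seq_along(peaks)) else names(peaks)
    m
}

#' Jaccard distance between binary rows
#'
#' \code{d(a, b) = 1 - |a & b| / |a | b|}, with the distance between two
#' all-zero rows defined as 0 (identical absence patterns).
#'
#' @param m binary matrix (rows are observations).
#' @return a \code{dist} object.
#' @export
binaryJaccardDist <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "numeric"
    inter <- tcrossprod(m)
    rs <- rowSums(m)
    uni <- outer(rs, rs, "+") - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0
    as.dist(d)
}

#' Cluster binary annotation rows
#'
#' Agglomerative hierarchical clustering of the rows of a binary occupancy
#' matrix under Jaccard distance with average linkage, cut into \code{k}
#' clusters. Rows are put into a canonical (lexicographic) order before
#' the tree is built, so the result is deterministic and invariant (up to
#' cluster renumbering) under row permutations even when tied merge
#' heights would otherwise make \code{hclust} order-sensitive. Cluster
#' labels are renumbered by first appearance in the input order. Rows with
#' identical absence patterns (all zero) are at distance 0 and fall into
#' one cluster.
#'
#' @param m binary matrix (e.g. from [annotatePeaks()]).
#' @param k number of clusters (>= 1; must not exceed the number of
#'   distinct rows).
#' @return named integer vector of cluster labels (1..k) with the
#'   \code{hclust} tree (on canonically ordered rows) attached as
#'   attribute \code{"tree"}.
#' @export
clusterBinary <- function(m, k = 5L) {
    m <- as.matrix(m)
    if (nrow(m) == 0L) stop("matrix is empty")
    if (k < 1L) stop("k must be >= 1")
    nDistinct <- nrow(unique(m))
    if (k > nDistinct)
        stop("k (", k, ") exceeds number of distinct rows (", nDistinct, ")")
    if (k == 1L) {
        lab <- setNames(rep(1L, nrow(m)), rownames(m))
        return(lab)
    }
    ord <- do.call(order, as.data.frame(unname(m)))
    tree <- hclust(binaryJaccardDist(m[ord, , drop = FALSE]),
                   method = "average")
    labCanon <- cutree(tree, k = k)
    inv <- integer(nrow(m))
    inv[ord] <- seq_len(nrow(m))
    lab <- labCanon[inv]
    lab <- match(lab, unique(lab))   # renumber by first appearance
    names(lab) <- rownames(m)
    attr(lab, "tree") <- tree
    lab
}

#' Display order for an annotation heatmap
#'
#' Rows grouped by cluster (ascending label), within-cluster ordered by row
#' sum descending, remaining ties by original row index.
#'
#' @param m binary matrix.
#' @param assignment cluster labels covering all rows of \code{m}.
#' @return integer row order.
#' @export
heatmapOrder <- function(m, assignment) {
    if (length(assignment) != nrow(m))
        stop("assignment must cover all rows")
    order(as.integer(assignment), -rowSums(m), seq_len(nrow(m)))
}

#' Render a black/white annotation heatmap
#'
#' Presence (1) is drawn black, absence (0) white, rows ordered by
#' [heatmapOrder()]. The rendered raster is invariant to permutations of
#' the input rows (up to cluster relabeling).
#'
#' @param m binary matrix.
#' @param assignment cluster labels for the rows of \code{m}.
#' @param file optional PNG path; when \code{NULL}, draws on the active
#'   device.
#' @return the row order, invisibly.
#' @export
plotAnnotationHeatmap <- function(m, assignment, file = NULL) {
    ord <- heatmapOrder(m, assignment)
    mm <- as.matrix(m)[ord, , drop = FALSE]
    if (!is.null(file)) {
        grDevices::png(file, width = 640, height = 800)
        on.exit(grDevices::dev.off())
    }
    graphics::image(t(mm[rev(seq_len(nrow(mm))), , drop = FALSE]),
        col = c("white", "black"), axes = FALSE,
        main = "Peak co-localization")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(mm)),
        labels = colnames(mm), las = 2, cex.axis = 0.8)
    sizes <- table(assignment)
    graphics::mtext(paste(sprintf("cluster %s: N=%d", names(sizes), sizes),
                          collapse = "  "), side = 3, line = 0.2, cex = 0.7)
    graphics::box()
    invisible(ord)
}
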