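# Strain-level profile analytics: presence calls, producing-strain sets,
# exclusive-compound counts, new-in-reference statistics, glog/Pareto
# transformation and hierarchical profile clustering.

#' Binary presence matrix from abundances
#'
#' A strain is called a producer of a compound when its abundance exceeds
#' `threshold` times the compound's maximum abundance. The default
#' threshold 0 calls any nonzero signal a detection, matching the usual
#' "producing strains" bookkeeping of compound tables; exact zeros are
#' never called present.
#'
#' @param m a [StrainCompoundMatrix-class] or non-negative matrix.
#' @param threshold fraction of the per-compound maximum, in `[0, 1)`.
#' @return binary matrix with attributes `threshold`.
#' @export
presenceMatrix <- function(m, threshold = 0) {
    stopifnot(threshold >= 0, threshold < 1)
    v <- if (is(m, "StrainCompoundMatrix")) abundances(m) else as.matrix(m)
    p <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
    for (j in seq_len(ncol(v))) {
        cut <- threshold * max(v[, j])
        p[, j] <- as.numeric(v[, j] > cut & v[, j] > 0)
    }
    attr(p, "threshold") <- threshold
    p
}

#' Producing-strain sets and exclusivity statistics
#'
#' @param p binary presence matrix (strains x compounds), e.g. from
#'   [presenceMatrix()].
#' @return list with `producers` (named list of strain sets per compound),
#'   `exclusiveCount` (compounds produced by exactly one strain),
#'   `perStrainCounts` (compounds produced per strain).
#' @export
producingStrains <- function(p) {
    p <- as.matrix(p)
    producers <- lapply(seq_len(ncol(p)), function(j)
        rownames(p)[p[, j] > 0])
    names(producers) <- colnames(p)
    list(producers = producers,
         exclusiveCount = sum(colSums(p > 0) == 1L),
         perStrainCounts = rowSums(p > 0))
}

#' How many newly found compounds the reference strain would have yielded
#'
#' Counts, among the newly identified compounds of a compound table, those
#' whose producing-strain set contains the reference strain -- the measure
#' of what a one-reference-strain prioritization would have recovered.
#'
#' @param records compound table as returned by [loadCompoundTable()] (needs
#'   list column `strains` and logical column `new`).
#' @param reference reference strain label.
#' @return list with `count`, `nNew` and `percent`.
#' @examples
#' tbl <- loadCompoundTable()
#' newInReference(tbl, "MM109")  # 3 of 10, 30%
#' @export
newInReference <- function(records, reference) {
    stopifnot(is.data.frame(records), "new" %in% names(records))
    newRec <- records[records$new, , drop = FALSE]
    if (nrow(newRec) == 0L) stop("no records flagged as new")
    hit <- vapply(newRec$strains, function(s) reference %in% s, logical(1L))
    list(count = sum(hit), nNew = nrow(newRec),
         percent = 100 * sum(hit) / nrow(newRec))
}

#' Generalized-log transform with Pareto scaling
#'
#' Variance stabilization for intensity matrices prior to clustering:
#' per cell \eqn{x \to \log((x + \sqrt{x^2 + \lambda^2})/2)}, then
#' per-column (per-compound) mean centering and division by the square root
#' of the column standard deviation (Pareto scaling). A zero-variance
#' column is centered to zeros with a warning rather than divided.
#'
#' @param m a [StrainCompoundMatrix-class] or numeric matrix.
#' @param lambda glog transition parameter; default: the smallest nonzero
#'   value of the matrix.
#' @return transformed numeric matrix.
#' @export
glogPareto <- function(m, lambda = NULL) {
    v <- if (is(m, "StrainCompoundMatrix")) abundances(m) else as.matrix(m)
    if (is.null(lambda)) {
        nz <- v[v > 0]
        lambda <- if (length(nz)) min(nz) else 1
    }
    stopifnot(lambda > 0)
    g <- log((v + sqrt(v^2 + lambda^2)) / 2)
    out <- g
    for (j in seq_len(ncol(g))) {
        col <- g[, j] - mean(g[, j])
        s <- sd(g[, j])
        if (s == 0) {
            warning("zero-variance column ", sQuote(colnames(g)[j]),
                    ": centered only")
            out[, j] <- col
        } else {
            out[, j] <- col / sqrt(s)
        }
    }
    out
}

#' Hierarchical clustering of metabolite profiles
#'
#' Agglomerative clustering with Euclidean distance and complete linkage on
#' both axes (strains from their compound profiles, compounds from their
#' strain distributions) of a transformed intensity matrix -- the standard
#' heatmap-ordering pipeline. Deterministic for a given matrix.
#'
#' @param tm transformed matrix, e.g. from [glogPareto()]; >= 2 rows.
#' @param k optional number of strain clusters to cut at.
#' @return list of class `ProfileClustering`: `rowTree`, `colTree`
#'   ([stats::hclust] objects), `transformed`, and `rowClusters` when `k`
#'   is given.
#' @export
clusterProfiles <- function(tm, k = NULL) {
    tm <- as.matrix(tm)
    if (nrow(tm) < 2L) stop("need at least 2 rows to cluster")
    rowTree <- hclust(dist(tm, method = "euclidean"), method = "complete")
    colTree <- if (ncol(tm) >= 2L)
        hclust(dist(t(tm), method = "euclidean"), method = "complete")
    else NULL
    out <- list(rowTree = rowTree, colTree = colTree, transformed = tm)
    if (!is.null(k)) out$rowClusters <- cutree(rowTree, k = k)
    class(out) <- "ProfileClustering"
    out
}

#' @export
print.ProfileClustering <- function(x, ...) {
    cat("ProfileClustering:", nrow(x$transformed), "rows x",
        ncol(x$transformed), "columns (Euclidean / complete linkage)\n")
    invisible(x)
}

#' Export a profile clustering
#'
#' Writes each axis dendrogram as Newick (via ape) and, when cluster labels
#' are present, a flat cluster-label TSV.
#'
#' @param pc a `ProfileClustering` from [clusterProfiles()].
#' @param prefix output path prefix.
#' @return paths written, invisibly.
#' @importFrom ape as.phylo write.tree
#' @export
exportClustering <- function(pc, prefix) {
    paths <- character(0)
    p <- paste0(prefix, "_rows.nwk")
    ape::write.tree(ape::as.phylo(pc$rowTree), file = p)
    paths <- c(paths, p)
    if (!is.null(pc$colTree)) {
        p <- paste0(prefix, "_cols.nwk")
        ape::write.tree(ape::as.phylo(pc$colTree), file = p)
        paths <- c(paths, p)
    }
    if (!is.null(pc$rowClusters)) {
        p <- paste0(prefix, "_clusters.tsv")
        write.table(data.frame(label = names(pc$rowClusters),
                               cluster = pc$rowClusters),
                    p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}
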