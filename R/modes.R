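#' Select derepressed genes across four measures
#'
#' Takes the union of genes showing an increase (positive change) passing
#' the per-measure significance threshold in newly-synthesised mRNA, total
#' mRNA, mRNA stability or ribosome-protected mRNA. The default thresholds
#' (FDR < 0.1 for newly-synthesised, FDR < 0.001 for total, z > 2 for
#' stability, FDR < 0.05 for ribosome-protected) deliberately differ per
#' measure: the assays differ widely in sensitivity, and each threshold is
#' set so that the genes with the most evidence for change in that assay
#' contribute to the downstream clustering.
#'
#' @param diffNew,diffTotal,diffRibo differential tables
#'   (from [assayDiff()]) with \code{gene_id}, \code{lfc}, \code{fdr}.
#' @param stab stability table (from [stabilitySignificance()]) with
#'   \code{gene_id}, \code{score}, \code{z}.
#' @param fdrNew,fdrTotal,fdrRibo,zStab the four thresholds.
#' @return Character vector of selected gene ids (sorted).
#' @export
selectDerepressed <- function(diffNew, diffTotal, stab, diffRibo,
                              fdrNew = 0.1, fdrTotal = 0.001,
                              zStab = 2, fdrRibo = 0.05) {
  up <- function(tab, col, thr) {
    stopIfNot(all(c("gene_id", "lfc", col) %in% colnames(tab)),
              paste("differential table lacks column", col))
    as.character(tab$gene_id[tab$lfc > 0 & tab[[col]] < thr])
  }
  stopIfNot(all(c("gene_id", "score", "z") %in% colnames(stab)),
            "stability table needs gene_id, score and z")
  selStab <- as.character(stab$gene_id[stab$score > 0 & stab$z > zStab])
  sort(unique(c(up(diffNew, "fdr", fdrNew),
                up(diffTotal, "fdr", fdrTotal),
                selStab,
                up(diffRibo, "fdr", fdrRibo))))
}

#' Assemble the genes x measures z-score matrix
#'
#' @param genes gene ids (rows of the output).
#' @param diffNew,diffTotal,diffRibo,stab tables as in [selectDerepressed()].
#' @return Numeric matrix with columns \code{new}, \code{stability},
#'   \code{ribo}, \code{total}. Genes missing from a table get \code{NA}.
#' @export
modeMatrix <- function(genes, diffNew, diffTotal, stab, diffRibo) {
  pull <- function(tab, col = "z") {
    v <- structure(as.numeric(tab[[col]]), names = as.character(tab$gene_id))
    unname(v[genes])
  }
  cbind(new = pull(diffNew), stability = pull(stab),
        ribo = pull(diffRibo), total = pull(diffTotal))
}

#' Cluster genes into regulatory modes
#'
#' Hierarchically clusters genes on the correlation between their z-score
#' profiles across the newly-synthesised, stability and ribosome-protected
#' measures (1 - Pearson correlation as the distance, complete linkage),
#' and cuts the tree into \code{k} clusters. The total-mRNA z column, when
#' present, is carried along for reporting but excluded from the distance.
#' Cluster numbers are canonicalised by the lexicographically smallest gene
#' id they contain, so the partition is independent of input row order.
#'
#' @param zMatrix genes x measures matrix with rownames; clustering uses
#'   the \code{new}, \code{stability} and \code{ribo} columns.
#' @param k number of clusters (default 5).
#' @return A [RegulatoryModes-class] object. Rows with any non-finite value
#'   in the clustering columns, or with zero variance across them
#'   (undefined correlation), are excluded with a warning and listed in the
#'   \code{excluded} slot.
#' @export
clusterModes <- function(zMatrix, k = 5) {
  stopIfNot(k >= 2, "k must be >= 2")
  stopIfNot(!is.null(rownames(zMatrix)), "zMatrix needs gene ids as rownames")
  clustCols <- c("new", "stability", "ribo")
  stopIfNot(all(clustCols %in% colnames(zMatrix)),
            "zMatrix must have columns new, stability, ribo")
  X <- zMatrix[, clustCols, drop = FALSE]
  bad <- !apply(X, 1L, function(r) all(is.finite(r)) && stats::sd(r) > 0)
  if (any(bad))
    warning(sum(bad), " gene(s) with constant or non-finite profile excluded")
  excluded <- rownames(zMatrix)[bad]
  X <- X[!bad, , drop = FALSE]
  Z <- zMatrix[!bad, , drop = FALSE]
  stopIfNot(nrow(X) > k, "need more genes than clusters")
  ord <- order(rownames(X))          # order-independent input to hclust
  X <- X[ord, , drop = FALSE]
  Z <- Z[ord, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(X)))
  tree <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(tree, k = k)
  # renumber clusters by their smallest member gene id
  firstId <- vapply(split(names(raw), raw), min, character(1))
  relabel <- order(order(firstId))
  cl <- stats::setNames(as.integer(relabel[raw]), names(raw))
  new("RegulatoryModes", zMatrix = Z, cluster = cl, tree = tree,
      summary = summarizeClusterMatrix(Z, cl), excluded = excluded)
}

# Per-cluster median z per measure with categorical labels.
summarizeClusterMatrix <- function(zMatrix, cluster) {
  ks <- sort(unique(cluster))
  out <- NULL
  for (kk in ks) {
    med <- apply(zMatrix[cluster == kk, , drop = FALSE], 2L, stats::median,
                 na.rm = TRUE)
    row <- DataFrame(cluster = kk, n = sum(cluster == kk))
    for (m in colnames(zMatrix)) {
      row[[paste0("median_", m)]] <- med[[m]]
      row[[paste0("label_", m)]] <- zLabel(med[[m]])
    }
    out <- rbind(out, row)
  }
  out
}

# Categorical label for a median z-score: "++" above 1.2, "+" above 0.4,
# "-" below -0.4, blank otherwise.
zLabel <- function(m, up = 0.4, strongUp = 1.2, down = -0.4) {
  if (is.na(m)) return(NA_character_)
  if (m > strongUp) "++" else if (m > up) "+" else if (m < down) "-" else ""
}

#' Summarise regulatory-mode clusters
#'
#' @param modes a [RegulatoryModes-class] object.
#' @return \linkS4class{DataFrame} of per-cluster sizes, median z per
#'   measure and categorical labels ("++" median > 1.2, "+" median > 0.4,
#'   "-" median < -0.4, blank otherwise).
#' @export
summarizeClusters <- function(modes) {
  stopIfNot(is(modes, "RegulatoryModes"), "modes must be RegulatoryModes")
  modes@summary
}
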