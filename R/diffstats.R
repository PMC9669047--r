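#' Median-of-ratios size factors
#'
#' Computes per-sample library size factors as the median, over reference
#' genes, of the ratio between the gene's count in that sample and its
#' geometric mean across all samples. Reference genes are those with a
#' nonzero count in every sample.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(100, 200))
#' sizeFactorsMedianOfRatios(m)   # ratio 1:2, geometric mean 1
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  stopIfNot(all(counts >= 0), "counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no reference gene: every gene has a zero count in at least one sample",
         call. = FALSE)
  logGeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - logGeo))
  })
  names(sf) <- colnames(counts)
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param counts genes x samples matrix.
#' @param sizeFactors per-sample positive factors; computed with
#'   [sizeFactorsMedianOfRatios()] when missing.
#' @return Matrix of normalised counts.
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianOfRatios(counts)
  stopIfNot(length(sizeFactors) == ncol(counts),
            "need one size factor per sample")
  sweep(counts, 2L, sizeFactors, "/")
}

#' Fragments per kilobase per million mapped reads
#'
#' @param counts genes x samples matrix of read counts.
#' @param featureLengths per-gene feature length in nucleotides (> 0).
#' @param mappedTotals per-sample total mapped reads (> 0).
#' @return Matrix of FPKM values.
#' @examples
#' computeFPKM(matrix(100), featureLengths = 1000, mappedTotals = 1e6)  # 100
#' @export
computeFPKM <- function(counts, featureLengths, mappedTotals) {
  counts <- as.matrix(counts)
  stopIfNot(all(featureLengths > 0), "feature lengths must be > 0")
  stopIfNot(all(mappedTotals > 0), "mapped totals must be > 0")
  stopIfNot(length(featureLengths) == nrow(counts),
            "need one length per gene")
  stopIfNot(length(mappedTotals) == ncol(counts),
            "need one mapped total per sample")
  out <- counts / (featureLengths / 1e3)
  sweep(out, 2L, mappedTotals / 1e6, "/")
}

#' Filter a differential table on base mean
#'
#' Retains rows with \code{base_mean} strictly greater than the threshold.
#' FDR values are deliberately not recomputed after filtering: the filter is
#' applied post hoc to an already-adjusted table.
#'
#' @param diff DataFrame/data.frame with a \code{base_mean} column.
#' @param threshold base-mean cutoff (default 10; strict \code{>}).
#' @return The filtered table.
#' @export
filterExpressed <- function(diff, threshold = 10) {
  stopIfNot("base_mean" %in% colnames(diff), "diff must have a base_mean column")
  stopIfNot(threshold >= 0, "threshold must be >= 0")
  diff[diff$base_mean > threshold, , drop = FALSE]
}

#' Global z-score from log2 fold changes
#'
#' Scales a vector of (possibly shrunken, externally supplied) log2 fold
#' changes by the overall sample standard deviation of the vector, making
#' effect sizes comparable across datasets with different sensitivities.
#' No mean-centering is applied.
#'
#' @param lfc numeric vector of log2 fold changes (>= 2 finite values).
#' @return z = lfc / sd(lfc).
#' @examples
#' zScoreFromLFC(c(2, -2))   # +/- 1/sqrt(2)
#' @export
zScoreFromLFC <- function(lfc) {
  ok <- is.finite(lfc)
  stopIfNot(sum(ok) >= 2, "need at least two finite log2 fold changes")
  s <- stats::sd(lfc[ok])
  stopIfNot(s > 0, "standard deviation of lfc is zero")
  lfc / s
}

# Window membership for one point: focal first, then the w - 1 nearest other
# points by (|expression difference|, expression, id-rank).
.idWindow <- function(i, ord, pos, expr, idRank, w, G) {
  lo <- max(1L, pos - w)
  hi <- min(G, pos + w)
  cand <- ord[lo:hi]
  cand <- cand[cand != i]
  d <- abs(expr[cand] - expr[i])
  sel <- cand[order(d, expr[cand], idRank[cand])][seq_len(w - 1L)]
  c(i, sel)
}

#' Expression-local z statistic (intensity difference)
#'
#' For each gene, forms a window of the \code{w} genes with the most similar
#' mean expression (the focal gene always included) and standardises the
#' gene's difference value against the mean and standard deviation of the
#' differences within that window. This replaces a single global standard
#' deviation with a local one, so that genes are judged against peers of
#' similar expression, where measurement variance is comparable. Two-sided
#' standard-normal p-values and Benjamini-Hochberg FDR are attached.
#'
#' In pooled mode (\code{contrasts} supplied), windows are formed over the
#' union of all contrasts' (expression, difference) points so that the local
#' standard deviations are modelled together and z-scores are comparable
#' across contrasts; rows are reported per contrast.
#'
#' Window size is \code{w = min(G, max(minWindow, ceiling(windowFraction *
#' G)))}. Ties in expression are broken by gene id; among equally distant
#' neighbours the lower-expression gene is taken first (a pinned,
#' deterministic rule). A window whose differences are all identical yields
#' z = 0 (the focal gene necessarily equals the window mean).
#'
#' @param meanExpr per-gene mean expression (any monotone scale; windows use
#'   distances on this scale). Named, or names taken from \code{diff}.
#' @param diff per-gene difference (e.g. log2 fold change or standardised
#'   stability change), aligned with \code{meanExpr}.
#' @param windowFraction fraction of genes per window, in (0, 1].
#' @param minWindow lower bound on the window size (default 200).
#' @param contrasts optional character/factor labelling each point's
#'   contrast for pooled mode.
#' @return \linkS4class{DataFrame} with columns \code{gene_id},
#'   \code{mean_expr}, \code{diff}, \code{z}, \code{p}, \code{fdr} and, in
#'   pooled mode, \code{contrast}. FDR is computed within contrast.
#' @export
intensityDiff <- function(meanExpr, diff, windowFraction = 0.01,
                          minWindow = 200, contrasts = NULL) {
  stopIfNot(length(meanExpr) == length(diff),
            "meanExpr and diff must be aligned")
  stopIfNot(windowFraction > 0 && windowFraction <= 1,
            "windowFraction must be in (0, 1]")
  ids <- names(meanExpr)
  if (is.null(ids)) ids <- names(diff)
  if (is.null(ids)) ids <- sprintf("g%0*d", nchar(length(diff)),
                                   seq_along(diff))
  G <- length(diff)
  w <- min(G, max(minWindow, ceiling(windowFraction * G)))
  stopIfNot(w >= 3, "window size must be at least 3")
  ok <- is.finite(meanExpr) & is.finite(diff)
  stopIfNot(all(ok), "meanExpr and diff must be finite")

  idRank <- rank(ids, ties.method = "first")
  ord <- order(meanExpr, idRank)
  pos <- integer(G)
  pos[ord] <- seq_len(G)
  z <- numeric(G)
  for (i in seq_len(G)) {
    win <- .idWindow(i, ord, pos[i], meanExpr, idRank, w, G)
    dv <- diff[win]
    mu <- mean(dv)
    s <- stats::sd(dv)
    z[i] <- if (s > 0) (diff[i] - mu) / s else 0
  }
  p <- 2 * stats::pnorm(-abs(z))
  res <- DataFrame(gene_id = ids, mean_expr = as.numeric(meanExpr),
                   diff = as.numeric(diff), z = z, p = p)
  if (is.null(contrasts)) {
    res$fdr <- stats::p.adjust(p, method = "BH")
  } else {
    stopIfNot(length(contrasts) == G, "contrasts must label every point")
    res$contrast <- as.character(contrasts)
    res$fdr <- NA_real_
    for (ct in unique(res$contrast)) {
      sel <- res$contrast == ct
      res$fdr[sel] <- stats::p.adjust(res$p[sel], method = "BH")
    }
  }
  res
}

#' Differential table for one assay
#'
#' Normalises counts by median-of-ratios size factors, computes per-gene
#' base means and plain log2 fold changes between two genotype groups
#' (pseudocount 0.5 on the group means), and attaches expression-local
#' z, p and FDR from [intensityDiff()] using log2 base mean as the
#' expression axis.
#'
#' @param counts genes x samples count matrix, or a
#'   \code{SummarizedExperiment} whose first assay holds the counts.
#' @param genotype per-sample genotype labels (taken from
#'   \code{colData(counts)$genotype} for a \code{SummarizedExperiment}).
#' @param contrast length-2 character: (numerator, denominator) genotype,
#'   default \code{c("dKO", "control")}.
#' @param windowFraction,minWindow passed to [intensityDiff()].
#' @return \linkS4class{DataFrame} with \code{gene_id}, \code{base_mean},
#'   \code{lfc}, \code{z}, \code{p}, \code{fdr}.
#' @export
assayDiff <- function(counts, genotype = NULL,
                      contrast = c("dKO", "control"),
                      windowFraction = 0.01, minWindow = 200) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(genotype))
      genotype <- SummarizedExperiment::colData(counts)$genotype
    counts <- SummarizedExperiment::assay(counts, 1L)
  }
  counts <- as.matrix(counts)
  stopIfNot(!is.null(genotype) && length(genotype) == ncol(counts),
            "need a genotype label per sample")
  stopIfNot(all(contrast %in% genotype),
            "both contrast genotypes must be present")
  norm <- normalizeCounts(counts)
  baseMean <- rowMeans(norm)
  mNum <- rowMeans(norm[, genotype == contrast[1L], drop = FALSE])
  mDen <- rowMeans(norm[, genotype == contrast[2L], drop = FALSE])
  lfc <- log2((mNum + 0.5) / (mDen + 0.5))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("g%0*d", nchar(nrow(counts)),
                                   seq_len(nrow(counts)))
  expr <- log2(baseMean + 0.5)
  names(expr) <- ids
  idf <- intensityDiff(expr, lfc, windowFraction = windowFraction,
                       minWindow = minWindow)
  DataFrame(gene_id = ids, base_mean = unname(baseMean),
            lfc = unname(lfc), z = idf$z, p = idf$p, fdr = idf$fdr)
}
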