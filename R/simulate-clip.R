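#' Simulate 3'UTR annotation, sequences and crosslink-site tables
#'
#' Builds a synthetic 3'UTR per gene (log-normal lengths, genes laid
#' end-to-end with gaps on one chromosome, plus strand), plants one
#' AU-rich-element motif (DNA spelling \code{TATTTATT}) wholly inside the
#' 3'UTR of every bound gene, and emits per-replicate crosslink-site tables
#' for the configured CLIP datasets. Bound genes receive a high-read,
#' low-FDR site exactly at the planted motif (identical position across
#' replicates); background sites with uniform FDRs and low read counts are
#' scattered over random genes. Site FDRs are emitted directly
#' (Beta-distributed at planted sites, uniform at background) -- the
#' upstream peak-calling that would produce them is out of this package's
#' scope.
#'
#' @param truth a [KineticTruth-class] object; genes of class
#'   \code{direct_target} are the bound genes.
#' @param seed integer seed.
#' @param meanLogLen,sdLogLen log-normal parameters of 3'UTR length
#'   (defaults log(800), 0.6).
#' @param minLen minimum 3'UTR length in nt (default 50; always enough to
#'   carry the 8-nt motif).
#' @param datasets list describing the simulated CLIP datasets. Each
#'   element is a list with either \code{nRep} (HITS-CLIP-style individual
#'   replicates) or \code{groups} (iCLIP-style grouped antibody tables).
#' @param boundReadMean mean read count at planted sites (default 20).
#' @param bgSitesPerRep background sites per replicate (default
#'   \code{nGenes / 2}).
#' @param bgReadMean mean read count at background sites (default 2).
#' @param plantedFdrShape2 Beta(1, shape2) for planted-site FDRs
#'   (default 50).
#' @param gap gap between consecutive UTRs in nt (default 100).
#' @return List with \code{utr} (\code{GRanges} with metadata
#'   \code{gene_id}, \code{feature = "3UTR"}, \code{motif_offset}),
#'   \code{utrSeq} (\code{DNAStringSet} keyed by gene id) and \code{sites}
#'   (named list of BED6+1 data.frames, one per dataset:replicate, columns
#'   \code{chrom}, \code{start}, \code{end}, \code{name},
#'   \code{read_count}, \code{strand}, \code{fdr}).
#' @export
simulateUtrCrosslinks <- function(truth, seed = 1,
                                  meanLogLen = log(800), sdLogLen = 0.6,
                                  minLen = 50,
                                  datasets = list(
                                    hitsclip = list(nRep = 4L),
                                    iclip = list(groups = c("ab1", "ab2"))),
                                  boundReadMean = 20,
                                  bgSitesPerRep = NULL,
                                  bgReadMean = 2,
                                  plantedFdrShape2 = 50,
                                  gap = 100L) {
  stopIfNot(is(truth, "KineticTruth"), "truth must be KineticTruth")
  set.seed(subSeed(seed, "clip"))
  tt <- truth@truth
  ids <- as.character(tt$gene_id)
  G <- length(ids)
  if (is.null(bgSitesPerRep)) bgSitesPerRep <- max(10L, G %/% 2L)
  len <- pmax(minLen, round(stats::rlnorm(G, meanLogLen, sdLogLen)))
  motif <- "TATTTATT"
  mlen <- nchar(motif)
  stopIfNot(all(len >= mlen),
            "3'UTR shorter than the motif for a gene required to carry one")
  bound <- tt$effect_class == "direct_target"

  seqs <- vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  }, character(1))
  motifOffset <- rep(NA_integer_, G)
  for (i in which(bound)) {
    off <- sample.int(len[i] - mlen + 1L, 1L) - 1L   # 0-based offset
    substr(seqs[i], off + 1L, off + mlen) <- motif
    motifOffset[i] <- off
  }
  # scrub accidental motif occurrences from unbound genes so that motif
  # presence tracks the planted ground truth
  for (i in which(!bound)) {
    while (grepl(motif, seqs[i], fixed = TRUE)) {
      pos <- regexpr(motif, seqs[i], fixed = TRUE)
      substr(seqs[i], pos, pos) <- "C"
    }
  }
  starts <- cumsum(c(1L, utils::head(len + gap, -1L)))   # 1-based
  utr <- GRanges("chr1", IRanges(start = starts, width = len), strand = "+")
  names(utr) <- ids
  S4Vectors::mcols(utr) <- S4Vectors::DataFrame(
    gene_id = ids, feature = "3UTR", length = len,
    motif_offset = motifOffset)
  utrSeq <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))

  plantedPos0 <- starts - 1L + motifOffset + 3L   # crosslink within motif
  makeRep <- function(dsName, repName) {
    bi <- which(bound)
    pStart <- plantedPos0[bi]
    planted <- data.frame(
      chrom = "chr1", start = pStart, end = pStart + 1L,
      name = paste(dsName, repName, sep = ":"),
      read_count = stats::rnbinom(length(bi), mu = boundReadMean,
                                  size = 10) + 1L,
      strand = "+",
      fdr = stats::rbeta(length(bi), 1, plantedFdrShape2))
    gi <- sample.int(G, bgSitesPerRep, replace = TRUE)
    off <- vapply(gi, function(i) sample.int(len[i], 1L) - 1L, integer(1))
    bgStart <- starts[gi] - 1L + off
    bg <- data.frame(
      chrom = "chr1", start = bgStart, end = bgStart + 1L,
      name = paste(dsName, repName, sep = ":"),
      read_count = stats::rpois(bgSitesPerRep, bgReadMean) + 1L,
      strand = "+",
      fdr = stats::runif(bgSitesPerRep))
    tab <- rbind(planted, bg)
    tab <- tab[!duplicated(tab[, c("chrom", "start", "strand")]), ]
    tab[order(tab$start), ]
  }
  sites <- list()
  for (dsName in names(datasets)) {
    ds <- datasets[[dsName]]
    repNames <- if (!is.null(ds$groups)) ds$groups
                else paste0("rep", seq_len(ds$nRep))
    for (rn in repNames)
      sites[[paste(dsName, rn, sep = ":")]] <- makeRep(dsName, rn)
  }
  list(utr = utr, utrSeq = utrSeq, sites = sites)
}
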