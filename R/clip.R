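#' @importFrom GenomicRanges GRanges findOverlaps strand seqnames start end
#' @importFrom IRanges IRanges
NULL

# Fixed feature priority used when a site overlaps several features.
.featurePriority <- c("3UTR" = 1L, "CDS" = 2L, "5UTR" = 3L,
                      "intron" = 4L, "noncoding" = 5L)

# BED-like site table (0-based half-open single-nucleotide intervals) to
# GRanges (1-based).
.sitesToGRanges <- function(sites) {
  need <- c("chrom", "start", "end", "strand")
  stopIfNot(all(need %in% colnames(sites)),
            "site table needs chrom, start, end, strand")
  stopIfNot(all(sites$end > sites$start), "malformed interval: end <= start")
  GRanges(sites$chrom,
          IRanges(start = sites$start + 1L, end = sites$end),
          strand = sites$strand)
}

#' Assign crosslink sites to genes and features
#'
#' Strand-aware assignment of single-nucleotide crosslink sites to gene
#' features. A site overlapping multiple features is assigned to a 3'UTR if
#' any overlapping feature is one; otherwise by the fixed priority
#' 3'UTR > CDS > 5'UTR > intron > non-coding, with ties at equal priority
#' broken by the smallest gene id. Sites overlapping nothing are labelled
#' \code{intergenic}.
#'
#' @param sites data.frame of sites in BED-like coordinates (columns
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, and typically
#'   \code{read_count}, \code{fdr}).
#' @param features \code{GRanges} of gene features with metadata columns
#'   \code{gene_id} and \code{feature} (values among \code{3UTR},
#'   \code{CDS}, \code{5UTR}, \code{intron}, \code{noncoding}).
#' @return \code{sites} with \code{gene_id} and \code{feature} columns
#'   appended.
#' @export
annotateSites <- function(sites, features) {
  stopIfNot(is(features, "GRanges"), "features must be a GRanges")
  md <- S4Vectors::mcols(features)
  stopIfNot(all(c("gene_id", "feature") %in% colnames(md)),
            "features needs gene_id and feature metadata columns")
  feat <- as.character(md$feature)
  stopIfNot(all(feat %in% names(.featurePriority)),
            "unknown feature type in annotation")
  gr <- .sitesToGRanges(sites)
  hits <- findOverlaps(gr, features, ignore.strand = FALSE)
  gene <- rep(NA_character_, nrow(sites))
  ftr <- rep("intergenic", nrow(sites))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    prio <- .featurePriority[feat[s]]
    gid <- as.character(md$gene_id)[s]
    ord <- order(q, prio, gid)
    first <- !duplicated(q[ord])
    gene[q[ord][first]] <- gid[ord][first]
    ftr[q[ord][first]] <- feat[s][ord][first]
  }
  sites$gene_id <- gene
  sites$feature <- ftr
  sites
}

#' Call 3'UTR targets from grouped iCLIP replicates (two antibodies)
#'
#' A gene is designated a target if, for each of the two antibody groups, at
#' least one crosslink site with FDR below \code{alpha} falls within the
#' gene's 3'UTR.
#'
#' @param groupedSites named list of exactly two annotated site tables (see
#'   [annotateSites()]), one per antibody group.
#' @param alpha site-level FDR threshold (default 0.05).
#' @param dataset dataset label for the returned object.
#' @param summary optional per-gene summary table from
#'   [summarizeCrosslinks()].
#' @return A [ClipTargets-class] object.
#' @export
callTargetsIclip <- function(groupedSites, alpha = 0.05, dataset = "iCLIP",
                             summary = NULL) {
  stopIfNot(is.list(groupedSites) && length(groupedSites) == 2L,
            "need exactly two antibody groups")
  perGroup <- lapply(groupedSites, function(tab) {
    stopIfNot(all(c("gene_id", "feature", "fdr") %in% colnames(tab)),
              "sites must be annotated (gene_id, feature, fdr)")
    unique(tab$gene_id[!is.na(tab$gene_id) & tab$feature == "3UTR" &
                         tab$fdr < alpha])
  })
  targets <- sort(Reduce(intersect, perGroup))
  if (is.null(summary)) summary <- DataFrame(gene_id = character(),
                                             reads = numeric(),
                                             score = numeric())
  new("ClipTargets", dataset = dataset, targets = targets, summary = summary)
}

#' Call 3'UTR targets from individual HITS-CLIP replicates
#'
#' A gene is designated a target if an identical significant crosslink site
#' (same chromosome, position and strand, FDR below \code{alpha}) is found
#' within its 3'UTR in at least \code{minReplicates} replicates. An
#' overlap-window variant is available through \code{tolerance}: sites
#' within \code{tolerance} nucleotides are treated as reproducing the same
#' site (off by default; the literal rule is exact positional identity).
#'
#' @param replicateSites list of annotated site tables, one per replicate.
#' @param alpha site-level FDR threshold (default 0.05).
#' @param minReplicates required number of replicates sharing the site
#'   (default 2).
#' @param tolerance positional tolerance in nucleotides (default 0 = exact).
#' @param dataset dataset label.
#' @param summary optional per-gene summary table.
#' @return A [ClipTargets-class] object.
#' @export
callTargetsHitsclip <- function(replicateSites, alpha = 0.05,
                                minReplicates = 2, tolerance = 0,
                                dataset = "HITS-CLIP", summary = NULL) {
  stopIfNot(is.list(replicateSites) && length(replicateSites) >= 1L,
            "replicateSites must be a non-empty list")
  sig <- NULL
  for (r in seq_along(replicateSites)) {
    tab <- replicateSites[[r]]
    stopIfNot(all(c("gene_id", "feature", "fdr", "chrom", "start",
                    "strand") %in% colnames(tab)),
              "sites must be annotated tables with coordinates")
    keep <- !is.na(tab$gene_id) & tab$feature == "3UTR" & tab$fdr < alpha
    if (!any(keep)) next
    sig <- rbind(sig, data.frame(rep = r,
                                 gene_id = tab$gene_id[keep],
                                 chrom = tab$chrom[keep],
                                 start = tab$start[keep],
                                 strand = tab$strand[keep]))
  }
  targets <- character()
  if (!is.null(sig)) {
    if (tolerance == 0) {
      key <- paste(sig$gene_id, sig$chrom, sig$start, sig$strand, sep = "\r")
      nrep <- tapply(sig$rep, key, function(x) length(unique(x)))
      hit <- names(nrep)[nrep >= minReplicates]
      targets <- sort(unique(vapply(strsplit(hit, "\r", fixed = TRUE),
                                    `[[`, character(1), 1L)))
    } else {
      for (g in unique(sig$gene_id)) {
        sg <- sig[sig$gene_id == g, ]
        for (i in seq_len(nrow(sg))) {
          near <- sg$chrom == sg$chrom[i] & sg$strand == sg$strand[i] &
            abs(sg$start - sg$start[i]) <= tolerance
          if (length(unique(sg$rep[near])) >= minReplicates) {
            targets <- c(targets, g)
            break
          }
        }
      }
      targets <- sort(unique(targets))
    }
  }
  if (is.null(summary)) summary <- DataFrame(gene_id = character(),
                                             reads = numeric(),
                                             score = numeric())
  new("ClipTargets", dataset = dataset, targets = targets, summary = summary)
}

#' Per-gene 3'UTR crosslink summary score
#'
#' Sums the reads at a gene's 3'UTR crosslink sites with FDR below
#' \code{fdrCap} (replicate-pooled input; duplicate rows at the same
#' position are aggregated first, reads summed and the smallest FDR kept).
#' Genes with a positive sum are "detected"; each detected gene's sum is
#' normalised to the 90th percentile of detected sums (linear interpolation
#' between order statistics) and log2-transformed, with no pseudocount.
#'
#' @param mergedSites annotated, replicate-pooled site table.
#' @param fdrCap FDR cap for contributing sites (default 0.25).
#' @return \linkS4class{DataFrame} with \code{gene_id}, \code{reads} (the
#'   raw sum) and \code{score} (log2 of the q90-normalised sum), detected
#'   genes only, plus the percentile value in \code{metadata()$q90}.
#' @export
summarizeCrosslinks <- function(mergedSites, fdrCap = 0.25) {
  tab <- mergedSites
  stopIfNot(all(c("gene_id", "feature", "fdr", "read_count", "chrom",
                  "start", "strand") %in% colnames(tab)),
            "sites must be annotated and carry read_count")
  tab <- tab[!is.na(tab$gene_id) & tab$feature == "3UTR", , drop = FALSE]
  if (nrow(tab)) {
    key <- paste(tab$gene_id, tab$chrom, tab$start, tab$strand, sep = "\r")
    reads <- tapply(tab$read_count, key, sum)
    fdr <- tapply(tab$fdr, key, min)
    gene <- vapply(strsplit(names(reads), "\r", fixed = TRUE),
                   `[[`, character(1), 1L)
    keep <- fdr < fdrCap
    S <- tapply(as.numeric(reads[keep]), gene[keep], sum)
  } else S <- numeric()
  S <- S[S > 0]
  if (!length(S)) stop("no detected genes", call. = FALSE)
  q90 <- unname(stats::quantile(as.numeric(S), 0.9, type = 7))
  res <- DataFrame(gene_id = names(S), reads = as.numeric(S),
                   score = log2(as.numeric(S) / q90))
  res <- res[order(res$gene_id), ]
  metadata(res)$q90 <- q90
  res
}

#' Count motif occurrences in 3'UTR sequences
#'
#' Counts possibly overlapping occurrences of a nucleotide motif in each
#' sequence. RNA and DNA spellings are equivalent (T and U are normalised).
#'
#' @param sequences named character vector or \code{DNAStringSet} of 3'UTR
#'   sequences keyed by gene id.
#' @param motif nucleotide string; default \code{UAUUUAUU}, the high-
#'   affinity AU-rich element core bound by ZFP36-family proteins.
#' @return \linkS4class{DataFrame} with \code{gene_id}, \code{count},
#'   \code{contains}.
#' @examples
#' scanMotif(c(g1 = "UAUUUAUUUAUU"))$count   # 2 overlapping occurrences
#' @export
scanMotif <- function(sequences, motif = "UAUUUAUU") {
  stopIfNot(nchar(motif) > 0, "motif must be non-empty")
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(sequences))
  seqs <- normalizeTU(sequences)
  motif <- normalizeTU(motif)
  stopIfNot(!grepl("[^ACGTN]", motif),
            "motif contains non-nucleotide characters")
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequences contain non-nucleotide characters", call. = FALSE)
  subj <- Biostrings::DNAStringSet(seqs)
  count <- Biostrings::vcountPattern(motif, subj)
  DataFrame(gene_id = ids, count = count, contains = count >= 1L)
}

#' Sliding-window average of per-base conservation scores
#'
#' Centred moving average with an odd window; at the sequence edges the
#' window shrinks to the available bases.
#'
#' @param scores numeric vector of per-base scores.
#' @param window odd window width in bases (default 7).
#' @return Numeric vector of smoothed scores, same length.
#' @examples
#' smoothConservation(c(0, 0, 0, 7, 0, 0, 0))   # centre 1, edges 1.75 etc.
#' @export
smoothConservation <- function(scores, window = 7) {
  stopIfNot(length(scores) > 0, "empty score vector")
  stopIfNot(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  n <- length(scores)
  h <- (window - 1L) / 2L
  cs <- cumsum(c(0, scores))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
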