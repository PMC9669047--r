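# Shared fixtures built in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# A small 3'UTR annotation: five genes side by side on chr1 (+ strand).
toyUtr <- function(n = 5, width = 500, gap = 500) {
  starts <- seq(1, by = width + gap, length.out = n)
  gr <- GRanges("chr1", IRanges(starts, width = width), strand = "+")
  ids <- paste0("g", seq_len(n))
  names(gr) <- ids
  mcols(gr) <- S4Vectors::DataFrame(gene_id = ids, feature = "3UTR")
  gr
}

# Crosslink-site table in BED-like coordinates.
toySites <- function(start, read_count = 1, fdr = 0.01, strand = "+",
                     chrom = "chr1", name = "ds:r1") {
  data.frame(chrom = chrom, start = start, end = start + 1L, name = name,
             read_count = read_count, strand = strand, fdr = fdr)
}

# Matched-controls universe with named expression and UTR-length vectors.
toyUniverse <- function(G, seed = 1, sdExpr = 2, meanLogLen = log(800),
                        sdLogLen = 0.6) {
  set.seed(seed)
  ids <- sprintf("g%05d", seq_len(G))
  list(ids = ids,
       expr = stats::setNames(stats::rnorm(G, 5, sdExpr), ids),
       len = stats::setNames(round(stats::rlnorm(G, meanLogLen, sdLogLen)),
                             ids))
}

# Run the three-fraction pipeline (normalise, correction factors,
# half-lives) on a simulated bundle of counts; returns the pieces tests
# need.
runStabilityPipeline <- function(truth, design, samples = NULL, seed = 1,
                                 grouping = "genotype.batch") {
  cnt <- simulateFractionCounts(truth, design, samples = samples,
                                seed = seed)
  norm <- lapply(cnt, function(se) normalizeCounts(assay(se)))
  cf <- estimateCorrectionFactors(norm$total, norm$new, norm$pre)
  cd <- colData(cnt$new)
  grp <- switch(grouping,
                genotype.batch = paste(cd$genotype, cd$batch, sep = "."),
                genotype = as.character(cd$genotype),
                all = rep("all", ncol(norm$new)))
  hl <- estimateHalfLives(norm$new, norm$pre, cf, grouping = grp,
                          tLabel = design@tLabel)
  list(counts = cnt, norm = norm, factors = cf, halflives = hl)
}
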