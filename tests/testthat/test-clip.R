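test_that("site annotation prioritises 3'UTRs and respects strand", {
  feats <- GRanges("chr1",
                   IRanges(start = c(101, 301, 301, 601),
                           end = c(300, 500, 500, 700)),
                   strand = c("+", "+", "+", "+"))
  mcols(feats) <- S4Vectors::DataFrame(
    gene_id = c("A", "A", "B", "C"),
    feature = c("3UTR", "CDS", "3UTR", "3UTR"))
  s <- toySites(start = c(150, 350, 650, 650))
  s$strand <- c("+", "+", "+", "-")
  ann <- annotateSites(s, feats)
  expect_equal(ann$gene_id[1], "A")          # only A's 3'UTR
  expect_equal(ann$feature[1], "3UTR")
  # overlaps A's CDS and B's 3'UTR: the 3'UTR wins
  expect_equal(ann$gene_id[2], "B")
  expect_equal(ann$feature[2], "3UTR")
  expect_equal(ann$gene_id[3], "C")
  # strand mismatch: intergenic
  expect_true(is.na(ann$gene_id[4]))
  expect_equal(ann$feature[4], "intergenic")
  expect_error(annotateSites(data.frame(chrom = "chr1", start = 10,
                                        end = 10, strand = "+"), feats),
               "malformed")
})

test_that("iCLIP targets require both antibodies in the 3'UTR", {
  utr <- toyUtr(3)
  ab1 <- annotateSites(toySites(start = c(10, 520), fdr = c(0.04, 0.2)),
                       utr)
  ab2 <- annotateSites(toySites(start = 15, fdr = 0.01), utr)
  ct <- callTargetsIclip(list(ab1, ab2))
  expect_equal(targetGenes(ct), "g1")    # fdr 0.04 + 0.01 in g1's 3'UTR
  # only one antibody qualifying: no target
  ab2b <- annotateSites(toySites(start = 15, fdr = 0.5), utr)
  expect_equal(length(targetGenes(callTargetsIclip(list(ab1, ab2b)))), 0)
  # qualifying sites in a CDS don't count
  cds <- toyUtr(1)
  mcols(cds)$feature <- "CDS"
  c1 <- annotateSites(toySites(start = 10, fdr = 0.01), cds)
  expect_equal(length(targetGenes(callTargetsIclip(list(c1, c1)))), 0)
  expect_error(callTargetsIclip(list(ab1)), "two antibody groups")
})

test_that("HITS-CLIP targets require an identical site in >= 2 replicates", {
  utr <- toyUtr(2)
  r1 <- annotateSites(toySites(start = 100), utr)
  r2 <- annotateSites(toySites(start = 101), utr)
  r3 <- annotateSites(toySites(start = 100), utr)
  # site at 100 in replicates 1 and 3: target
  expect_equal(targetGenes(callTargetsHitsclip(list(r1, r2, r3))), "g1")
  # 100 vs 101 only: not identical, no target
  expect_equal(length(targetGenes(callTargetsHitsclip(list(r1, r2)))), 0)
  # one replicate only: never a target
  expect_equal(length(targetGenes(callTargetsHitsclip(list(r1)))), 0)
  # the overlap-window variant accepts near-identical sites
  ctTol <- callTargetsHitsclip(list(r1, r2), tolerance = 2)
  expect_equal(targetGenes(ctTol), "g1")
})

test_that("target calling is monotone in sites and alpha", {
  utr <- toyUtr(3)
  r1 <- annotateSites(toySites(start = c(100, 600), fdr = c(0.04, 0.2)),
                      utr)
  r2 <- annotateSites(toySites(start = c(100, 600), fdr = c(0.03, 0.1)),
                      utr)
  t1 <- targetGenes(callTargetsHitsclip(list(r1, r2), alpha = 0.05))
  t2 <- targetGenes(callTargetsHitsclip(list(r1, r2), alpha = 0.25))
  expect_true(all(t1 %in% t2))     # raising alpha never shrinks the set
  # adding a qualifying site never removes a gene
  r2b <- rbind(r2, annotateSites(toySites(start = 1100, fdr = 0.01), utr))
  r1b <- rbind(r1, annotateSites(toySites(start = 1100, fdr = 0.01), utr))
  t3 <- targetGenes(callTargetsHitsclip(list(r1b, r2b), alpha = 0.05))
  expect_true(all(t1 %in% t3))
})

test_that("crosslink summaries follow the FDR cap and q90 normalisation", {
  utr <- toyUtr(1)
  s <- annotateSites(toySites(start = c(10, 20, 30),
                              read_count = c(5, 7, 3),
                              fdr = c(0.2, 0.3, 0.05)), utr)
  sc <- summarizeCrosslinks(s)
  expect_equal(sc$reads, 8)           # the 0.3-FDR site is excluded
  # ten genes with sums 1..10: q90 = 9.1 (linear interpolation)
  utr10 <- toyUtr(10)
  starts <- GenomicRanges::start(utr10) + 9
  s10 <- annotateSites(toySites(start = starts, read_count = 1:10,
                                fdr = 0.01), utr10)
  sc10 <- summarizeCrosslinks(s10)
  expect_equal(S4Vectors::metadata(sc10)$q90, 9.1)
  expected <- log2((1:10) / 9.1)
  got <- structure(sc10$score, names = sc10$gene_id)
  expect_equal(unname(got[paste0("g", 1:10)]), expected)
  # a gene whose sum equals the q90 scores exactly 0
  utr2 <- toyUtr(2)
  s2 <- annotateSites(toySites(start = GenomicRanges::start(utr2) + 4,
                               read_count = c(5, 5), fdr = 0.01), utr2)
  sc2 <- summarizeCrosslinks(s2)
  expect_equal(sc2$score, c(0, 0))
  expect_error(summarizeCrosslinks(s[0, ]), "no detected genes")
})

test_that("crosslink summaries are invariant to row order and splitting", {
  utr <- toyUtr(3)
  s <- annotateSites(toySites(start = c(10, 20, 510, 1020),
                              read_count = c(5, 7, 2, 9),
                              fdr = c(0.1, 0.2, 0.01, 0.05)), utr)
  base <- summarizeCrosslinks(s)
  shuffled <- summarizeCrosslinks(s[c(3, 1, 4, 2), ])
  expect_equal(base, shuffled)
  # split one site's reads across duplicate rows at the same position
  split <- rbind(s, s[2, ])
  split$read_count[c(2, 5)] <- c(3, 4)
  expect_equal(summarizeCrosslinks(split), base)
})

test_that("motif scanning counts overlaps and normalises T/U", {
  res <- scanMotif(c(gx = "UAUUUAUUUAUU"))
  expect_equal(res$count, 2)       # overlapping occurrences
  expect_true(res$contains)
  expect_equal(scanMotif(c(g = "TATTTATT"))$count, 1)  # DNA spelling
  expect_equal(scanMotif(c(g = "UAUU"))$count, 0)      # shorter than motif
  expect_error(scanMotif(c(g = "TAXTTATT")), "non-nucleotide")
  # exhaustive position scan oracle on a random sequence
  set.seed(1)
  sq <- paste(sample(c("A", "T"), 2000, TRUE, prob = c(0.6, 0.4)),
              collapse = "")
  oracle <- sum(vapply(1:(nchar(sq) - 7), function(i)
    substr(sq, i, i + 7) == "TATTTATT", logical(1)))
  expect_equal(scanMotif(c(g = sq))$count, oracle)
})

test_that("conservation smoothing averages with shrinking edges", {
  expect_equal(smoothConservation(rep(3, 10)), rep(3, 10))
  v <- c(0, 0, 0, 7, 0, 0, 0)
  sm <- smoothConservation(v, 7)
  expect_equal(sm[4], 1)
  expect_equal(sm[1], 7 / 4)       # mean of the first 4 positions
  # full shrinking-window oracle
  oracle <- vapply(seq_along(v), function(i) {
    lo <- max(1, i - 3); hi <- min(length(v), i + 3)
    mean(v[lo:hi])
  }, numeric(1))
  expect_equal(sm, oracle)
  expect_equal(smoothConservation(v, 1), v)
  expect_error(smoothConservation(v, 4), "odd")
  expect_error(smoothConservation(numeric(0)), "empty")
})
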