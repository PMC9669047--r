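test_that("generation is deterministic under a fixed seed", {
  t1 <- simulateKinetics(100, seed = 7)
  t2 <- simulateKinetics(100, seed = 7)
  expect_identical(truthTable(t1), truthTable(t2))
  expect_identical(t1@batchFactors, t2@batchFactors)
  b1 <- simulateBundle(nGenes = 60, seed = 7,
                       design = labelingDesign(depth = 1e4),
                       riboDepth = 1e4)
  b2 <- simulateBundle(nGenes = 60, seed = 7,
                       design = labelingDesign(depth = 1e4),
                       riboDepth = 1e4)
  expect_identical(SummarizedExperiment::assay(b1@counts$total),
                   SummarizedExperiment::assay(b2@counts$total))
  expect_identical(b1@crosslinks, b2@crosslinks)
  expect_identical(b1@metabolites$table, b2@metabolites$table)
})

test_that("effect-class proportions follow the configuration exactly", {
  t0 <- simulateKinetics(100, seed = 7, fracDirect = 0, fracIndirect = 0)
  expect_true(all(truthTable(t0)$effect_class == "null"))
  t1 <- simulateKinetics(97, seed = 1, fracDirect = 0.1,
                         fracIndirect = 0.2)
  cls <- table(truthTable(t1)$effect_class)
  expect_equal(unname(cls[["direct_target"]]), floor(0.1 * 97))
  expect_equal(unname(cls[["indirect_transcriptional"]]), floor(0.2 * 97))
  expect_error(simulateKinetics(0), "positive")
  expect_error(simulateKinetics(10, fracDirect = 0.7, fracIndirect = 0.6),
               "at most 1")
  # direct targets decay slower and translate more in the knockout;
  # indirect genes transcribe more
  tt <- truthTable(t1)
  expect_true(all(tt$dKO_delta_mult[tt$effect_class == "direct_target"] < 1))
  expect_true(all(tt$dKO_te_mult[tt$effect_class == "direct_target"] > 1))
  expect_true(all(
    tt$dKO_alpha_mult[tt$effect_class == "indirect_transcriptional"] > 1))
})

test_that("the decay-rate distribution hits the configured median", {
  tt <- truthTable(simulateKinetics(5000, seed = 11))
  medT <- median(log(2) / tt$delta)
  expect_lt(abs(medT / 4 - 1), 0.1)
})

test_that("expected fraction means obey the labelling model exactly", {
  truth <- simulateKinetics(50, seed = 3)
  cnt <- simulateFractionCounts(truth, labelingDesign(), seed = 3)
  mu <- lapply(cnt, function(se) SummarizedExperiment::assay(se, "mu"))
  # labelled + pre-existing expected means equal the total expected mean
  expect_equal(unname(mu$new + mu$pre), unname(mu$total),
               tolerance = 1e-12)
  # delta = ln2, t = 1 -> labelled share exactly one half
  tt <- truthTable(truth)
  tHalf1 <- new("KineticTruth",
                truth = S4Vectors::DataFrame(
                  gene_id = "g1", alpha = 10, delta = log(2), te = 1,
                  effect_class = "null", dispersion = 0,
                  control_alpha_mult = 1, control_delta_mult = 1,
                  control_te_mult = 1),
                batchFactors = matrix(1, 1, 1,
                                      dimnames = list("g1", "b1")),
                genotypes = "control", seed = 1L)
  c1 <- simulateFractionCounts(tHalf1, labelingDesign(), seed = 1)
  m1 <- lapply(c1, function(se) SummarizedExperiment::assay(se, "mu"))
  expect_equal(unname(m1$new[1, 1] / m1$total[1, 1]), 0.5)
  # very fast decay: labelled share -> 1, pre-existing mean -> 0
  tFast <- tHalf1
  tFast@truth$delta <- 50
  cF <- simulateFractionCounts(tFast, labelingDesign(), seed = 1)
  mF <- lapply(cF, function(se) SummarizedExperiment::assay(se, "mu"))
  expect_lt(mF$pre[1, 1] / mF$total[1, 1], 1e-20)
})

test_that("zero dispersion gives Poisson counts around the stated means", {
  # all genes at t1/2 = 1 h: empirical new/total ratio recovers theta = 0.5
  G <- 100
  tt <- S4Vectors::DataFrame(
    gene_id = sprintf("g%03d", 1:G), alpha = rep(100, G),
    delta = rep(log(2), G), te = 1, effect_class = "null", dispersion = 0,
    control_alpha_mult = 1, control_delta_mult = 1, control_te_mult = 1)
  truth <- new("KineticTruth", truth = tt,
               batchFactors = matrix(1, G, 1,
                                     dimnames = list(tt$gene_id, "b1")),
               genotypes = "control", seed = 1L)
  cnt <- simulateFractionCounts(truth, labelingDesign(depth = 1e6),
                                seed = 4)
  a <- function(se) SummarizedExperiment::assay(se)
  ratio <- sum(a(cnt$new)) / (sum(a(cnt$new)) + sum(a(cnt$pre)))
  expect_lt(abs(ratio / 0.5 - 1), 0.02)
  # Poisson: variance of standardised residuals near 1
  muN <- SummarizedExperiment::assay(cnt$new, "mu")
  resid <- (a(cnt$new) - muN) / sqrt(muN)
  expect_lt(abs(var(as.numeric(resid)) - 1), 0.35)
})

test_that("ribosome counts track abundance times translation efficiency", {
  # te doubled in dKO with abundance unchanged: footprint ratio 2 exactly
  G <- 200
  tt <- S4Vectors::DataFrame(
    gene_id = sprintf("g%03d", 1:G), alpha = rlnorm(G, log(50), 1),
    delta = rep(log(2) / 4, G), te = rep(1, G), effect_class = "null",
    dispersion = 0.02,
    control_alpha_mult = 1, control_delta_mult = 1, control_te_mult = 1,
    dKO_alpha_mult = 1, dKO_delta_mult = 1, dKO_te_mult = 2)
  truth <- new("KineticTruth", truth = tt,
               batchFactors = matrix(1, G, 1,
                                     dimnames = list(tt$gene_id, "b1")),
               genotypes = c("control", "dKO"), seed = 1L)
  se <- simulateRiboCounts(truth, depth = NA, seed = 5)
  mu <- SummarizedExperiment::assay(se, "mu")
  gt <- SummarizedExperiment::colData(se)$genotype
  expect_equal(rowMeans(mu[, gt == "dKO", drop = FALSE]) /
                 rowMeans(mu[, gt == "control", drop = FALSE]),
               setNames(rep(2, G), tt$gene_id))
  # equal te: footprints rank-correlate with abundance
  truth2 <- simulateKinetics(500, seed = 6, fracDirect = 0,
                             fracIndirect = 0, sdLogTE = 0)
  se2 <- simulateRiboCounts(truth2, depth = 1e6, seed = 6)
  tot <- truthTable(truth2)$alpha / truthTable(truth2)$delta
  fp <- rowMeans(SummarizedExperiment::assay(se2))
  expect_gt(cor(tot, fp, method = "spearman"), 0.95)
  # te = 0 silences a gene completely
  tt$te[1] <- 0
  truth0 <- new("KineticTruth", truth = tt,
                batchFactors = truth@batchFactors,
                genotypes = c("control", "dKO"), seed = 1L)
  se0 <- simulateRiboCounts(truth0, depth = NA, seed = 7)
  expect_true(all(SummarizedExperiment::assay(se0)[1, ] == 0))
})

test_that("planted ARE motifs land inside their 3'UTRs, consistently", {
  truth <- simulateKinetics(300, seed = 8, fracDirect = 0.1)
  clip <- simulateUtrCrosslinks(truth, seed = 8)
  mo <- S4Vectors::mcols(clip$utr)
  bound <- which(!is.na(mo$motif_offset))
  expect_gt(length(bound), 0)
  for (i in bound) {
    off <- mo$motif_offset[i]
    sq <- as.character(clip$utrSeq[[i]])
    expect_identical(substr(sq, off + 1, off + 8), "TATTTATT")
    expect_lte(off + 8, mo$length[i])   # wholly within the UTR
  }
  # motif presence tracks the planted ground truth exactly
  sm <- scanMotif(clip$utrSeq)
  tt <- truthTable(truth)
  expect_identical(sm$contains, tt$effect_class == "direct_target")
  # BED interval and FASTA agree: the planted crosslink site's position,
  # mapped back through the UTR coordinates, hits the motif
  ann <- annotateSites(clip$sites[[1]], clip$utr)
  planted <- ann[!is.na(ann$gene_id) & ann$fdr < 0.02 &
                   ann$read_count > 5, ]
  gi <- match(planted$gene_id[1], mo$gene_id)
  rel <- planted$start[1] - (GenomicRanges::start(clip$utr)[gi] - 1)
  expect_gte(rel, mo$motif_offset[gi])
  expect_lt(rel, mo$motif_offset[gi] + 8)
})

test_that("replicated crosslink sites make planted genes callable targets", {
  truth <- simulateKinetics(200, seed = 9, fracDirect = 0.1)
  clip <- simulateUtrCrosslinks(truth, seed = 9)
  ann <- lapply(clip$sites, annotateSites, features = clip$utr)
  hits <- ann[grep("^hitsclip", names(ann))]
  ct <- callTargetsHitsclip(hits)
  tt <- truthTable(truth)
  bound <- tt$gene_id[tt$effect_class == "direct_target"]
  expect_gte(mean(bound %in% targetGenes(ct)), 0.95)
  expect_lte(mean(!targetGenes(ct) %in% bound), 0.05)
})

test_that("metabolite table plants exact folds when noiseless", {
  mb <- simulateMetabolomics(seed = 10, noiseSdLog2 = 0)
  tab <- normalizeMetabolites(mb$metabolites$table,
                              mb$metabolites$internal_standard,
                              mode = "is")
  gt <- mb$metabolites$samples$genotype
  st <- metaboliteStats(tab, gt)
  planted <- mb$metabolites$true_fold
  got <- structure(st$fold, names = st$metabolite)
  expect_equal(got[names(planted)], planted, tolerance = 1e-9)
  expect_equal(nrow(tab), 52L)
})

test_that("noiseless spectra round-trip through the correction", {
  mb <- simulateMetabolomics(seed = 12, isoNoiseSdLog2 = 0)
  for (sp in mb$spectra) {
    res <- correctMID(sp)
    expect_lt(max(abs(mid(res) - sp$true_mid)), 1e-6)
  }
})
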