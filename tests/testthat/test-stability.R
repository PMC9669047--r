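test_that("correction factors are exact on noiseless mixtures", {
  set.seed(1)
  A <- matrix(runif(300, 20, 500), 100, 3)
  theta <- matrix(runif(300, 0.1, 0.9), 100, 3)
  L <- A * theta; U <- A * (1 - theta)
  cf <- estimateCorrectionFactors(2 * L + 0.5 * U, L, U)
  expect_equal(unname(meanFactors(cf)), c(2, 0.5), tolerance = 1e-10)
  cf2 <- estimateCorrectionFactors(L + U, L, U)
  expect_equal(unname(meanFactors(cf2)), c(1, 1), tolerance = 1e-10)
  expect_true(all(sampleFactors(cf)$valid))
})

test_that("correction factors are recovered within 10% under NB noise", {
  truth <- simulateKinetics(1500, seed = 2, fracDirect = 0,
                            fracIndirect = 0, meanLogAlpha = log(120))
  design <- labelingDesign(fractionScale = c(total = 1, new = 1 / 1.6,
                                             pre = 1 / 0.8))
  cnt <- simulateFractionCounts(truth, design, seed = 2)
  a <- function(se) SummarizedExperiment::assay(se)
  cf <- estimateCorrectionFactors(a(cnt$total), a(cnt$new), a(cnt$pre))
  mf <- meanFactors(cf)
  expect_lt(abs(mf[["cL"]] / 1.6 - 1), 0.1)
  expect_lt(abs(mf[["cU"]] / 0.8 - 1), 0.1)
})

test_that("samples with non-positive coefficients are flagged invalid", {
  set.seed(3)
  A <- runif(200, 100, 200)
  B <- runif(200, 1, 2)
  # total anti-correlated with the unlabelled fraction: cU comes out < 0
  Tm <- cbind(2 * A - 5 * B, 2 * A + 0.5 * B)
  L <- cbind(A, A); U <- cbind(B, B)
  cf <- estimateCorrectionFactors(Tm, L, U, method = "ols")
  expect_false(sampleFactors(cf)$valid[1])
  expect_true(sampleFactors(cf)$valid[2])
  # means use valid samples only
  expect_equal(unname(meanFactors(cf)), c(2, 0.5), tolerance = 1e-8)
})

test_that("half-life formulae and validity flags are exact", {
  # theta 0.5 -> t1/2 = 1 h; theta 0.75 -> 0.5 h; theta 1 -> invalid
  A <- 1000
  L <- matrix(c(0.5, 0.75, 1) * A)
  U <- matrix(c(0.5, 0.25, 0) * A)
  rownames(L) <- rownames(U) <- c("gA", "gB", "gC")
  cfUnit <- new("CorrectionFactors",
                samples = S4Vectors::DataFrame(sample = "s", cL = 1, cU = 1,
                                               valid = TRUE, r2 = 1,
                                               n_genes = 3L),
                meanCL = 1, meanCU = 1)
  hl <- estimateHalfLives(L, U, cfUnit, grouping = "g", tLabel = 1)
  expect_equal(hl$theta[1:2], c(0.5, 0.75))
  expect_equal(hl$half_life[1:2], c(1, 0.5))
  expect_false(hl$valid[3])
  expect_equal(hl$reason[3], "theta>=1")
  # t1/2 = ln2/delta and delta = -ln(1-theta)/t hold exactly on valid rows
  ok <- hl$valid
  expect_equal(hl$half_life[ok], log(2) / hl$delta[ok])
  expect_equal(hl$delta[ok], -log(1 - hl$theta[ok]))
})

test_that("half-life is strictly decreasing in theta", {
  theta <- seq(0.01, 0.99, by = 0.01)
  A <- 1e4
  L <- matrix(theta * A); U <- matrix((1 - theta) * A)
  rownames(L) <- rownames(U) <- sprintf("g%02d", seq_along(theta))
  cf <- new("CorrectionFactors",
            samples = S4Vectors::DataFrame(sample = "s", cL = 1, cU = 1,
                                           valid = TRUE, r2 = 1,
                                           n_genes = 99L),
            meanCL = 1, meanCU = 1)
  hl <- estimateHalfLives(L, U, cf, grouping = "g")
  expect_true(all(diff(hl$half_life) < 0))
})

test_that("noiseless fraction counts round-trip to the exact decay rates", {
  truth <- simulateKinetics(400, seed = 4, fracDirect = 0, fracIndirect = 0,
                            nBatches = 1, batchSdLog2 = 0)
  design <- labelingDesign(fractionScale = c(total = 1, new = 1 / 1.3,
                                             pre = 1 / 0.7))
  cnt <- simulateFractionCounts(truth, design, seed = 4)
  mus <- lapply(cnt, function(se) SummarizedExperiment::assay(se, "mu"))
  cf <- estimateCorrectionFactors(mus$total, mus$new, mus$pre)
  hl <- estimateHalfLives(mus$new, mus$pre, cf, grouping = rep("g", 2),
                          minCount = 0)
  tt <- truthTable(truth)
  ok <- hl$valid
  expect_true(all(ok))
  expect_equal(hl$delta[ok], unname(tt$delta[match(hl$gene_id[ok],
                                                   tt$gene_id)]),
               tolerance = 1e-6)
})

test_that("batch standardisation behaves as specified", {
  # one batch with d = [1, -1]: standardised values are +/- 1/sqrt(2)
  hl <- S4Vectors::DataFrame(
    gene_id = rep(c("gA", "gB"), 4),
    group = rep(c("dKO.b1", "control.b1", "dKO.b2", "control.b2"),
                each = 2),
    half_life = c(2, 0.5, 1, 1, 2, 0.5, 1, 1),
    valid = TRUE)
  ch <- standardizedStabilityChange(hl)
  expect_equal(sort(ch$z_b1), c(-1, 1) / sqrt(2))
  # duplicate batch: identical score
  expect_equal(ch$z_b1, ch$z_b2)
  expect_equal(ch$score, ch$z_b1)
  # single batch equals that batch's standardised values
  ch1 <- standardizedStabilityChange(hl[grepl("b1", hl$group), ])
  expect_equal(ch1$score, ch$z_b1)
  # swapping genotype labels negates everything exactly
  chSwap <- standardizedStabilityChange(hl,
                                        contrast = c("control", "dKO"))
  expect_equal(chSwap$score, -ch$score)
  expect_error(standardizedStabilityChange(
    S4Vectors::DataFrame(gene_id = c("gA", "gB", "gA", "gB"),
                         group = rep(c("dKO.b1", "control.b1"), each = 2),
                         half_life = c(2, 2, 1, 1), valid = TRUE)),
    "zero within-batch SD")
})

test_that("within-batch standardised changes have unit SD", {
  truth <- simulateKinetics(800, seed = 5)
  pipe <- runStabilityPipeline(truth, labelingDesign(depth = 5e5),
                               seed = 5)
  ch <- standardizedStabilityChange(pipe$halflives)
  for (b in c("b1", "b2")) {
    z <- ch[[paste0("z_", b)]]
    expect_equal(sd(z[!is.na(z)]), 1, tolerance = 1e-9)
  }
})

test_that("planted stabilised genes are recovered in the top score decile", {
  # two replicates per genotype and batch; 5% of genes twice as stable
  truth <- simulateKinetics(2000, seed = 6, fracDirect = 0.05,
                            fracIndirect = 0)
  samples <- expand.grid(genotype = c("control", "dKO"),
                         batch = c("b1", "b2"), replicate = 1:2,
                         stringsAsFactors = FALSE)
  pipe <- runStabilityPipeline(truth, labelingDesign(depth = 1e6),
                               samples = samples, seed = 6)
  ch <- standardizedStabilityChange(pipe$halflives)
  tt <- truthTable(truth)
  planted <- tt$gene_id[tt$effect_class == "direct_target"]
  sc <- structure(ch$score, names = ch$gene_id)
  top <- names(sort(sc, decreasing = TRUE))[seq_len(round(0.1 * length(sc)))]
  expect_gte(mean(planted %in% top), 0.8)
})

test_that("stability significance flags planted genes and handles nulls", {
  truth <- simulateKinetics(2000, seed = 6, fracDirect = 0.05,
                            fracIndirect = 0)
  samples <- expand.grid(genotype = c("control", "dKO"),
                         batch = c("b1", "b2"), replicate = 1:2,
                         stringsAsFactors = FALSE)
  pipe <- runStabilityPipeline(truth, labelingDesign(depth = 1e6),
                               samples = samples, seed = 6)
  ch <- standardizedStabilityChange(pipe$halflives)
  me <- rowMeans(cbind(pipe$norm$total, pipe$norm$new))
  sig <- stabilitySignificance(ch, me)
  tt <- truthTable(truth)
  planted <- sig$gene_id %in% tt$gene_id[tt$effect_class == "direct_target"]
  # z > 2 calls are strongly enriched for the planted stabilised genes
  expect_gt(mean(planted[sig$z > 2]), 10 * mean(planted))
  # all-zero differences give all-zero z
  ch0 <- ch
  ch0$score <- rep(0, nrow(ch0))
  sig0 <- stabilitySignificance(ch0, me)
  expect_true(all(sig0$z == 0))
})
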