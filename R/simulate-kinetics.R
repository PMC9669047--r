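#' Simulate ground-truth transcriptome kinetics
#'
#' Draws per-gene synthesis rates (alpha), first-order decay rates (delta)
#' and translation efficiencies (TE) from log-normal distributions, assigns
#' effect classes, and attaches genotype multipliers and per-batch
#' multiplicative abundance factors. Direct targets are derepressed
#' post-transcriptionally in the knockout genotype (slower decay and/or
#' higher TE); indirect effects act on synthesis.
#'
#' @param nGenes number of genes (> 0).
#' @param fracDirect,fracIndirect fractions of genes in the
#'   \code{direct_target} and \code{indirect_transcriptional} classes;
#'   exactly \code{floor(frac * nGenes)} genes each, summing to at most 1.
#' @param seed integer seed.
#' @param medianHalfLife median true half-life in hours (default 4).
#' @param sdLogHalfLife log-scale SD of the half-life distribution
#'   (default 0.8, spanning roughly 1-16 h).
#' @param meanLogAlpha,sdLogAlpha log-normal parameters of the synthesis
#'   rate (arbitrary transcript/h scale).
#' @param meanLogTE,sdLogTE log-normal parameters of translation
#'   efficiency.
#' @param dispersion negative-binomial dispersion, recycled per gene
#'   (default 0.05).
#' @param genotypes genotype levels; the first is the control/reference.
#' @param nBatches number of batches (default 2).
#' @param batchSdLog2 SD of the per-gene, per-batch log2 abundance factors
#'   (default 0.2).
#' @param directDeltaMult knockout decay multiplier for direct targets
#'   (default 0.5, i.e. twice as stable).
#' @param directTeMult knockout TE multiplier for direct targets
#'   (default 2).
#' @param indirectAlphaMult knockout synthesis multiplier for indirect
#'   genes (default 2).
#' @return A [KineticTruth-class] object.
#' @export
simulateKinetics <- function(nGenes, fracDirect = 0.05, fracIndirect = 0.05,
                             seed = 1,
                             medianHalfLife = 4, sdLogHalfLife = 0.8,
                             meanLogAlpha = log(50), sdLogAlpha = 1,
                             meanLogTE = 0, sdLogTE = 0.4,
                             dispersion = 0.05,
                             genotypes = c("control", "dKO"),
                             nBatches = 2, batchSdLog2 = 0.2,
                             directDeltaMult = 0.5, directTeMult = 2,
                             indirectAlphaMult = 2) {
  stopIfNot(nGenes > 0, "nGenes must be positive")
  stopIfNot(fracDirect >= 0 && fracIndirect >= 0 &&
              fracDirect + fracIndirect <= 1,
            "class fractions must be non-negative and sum to at most 1")
  set.seed(subSeed(seed, "kinetics"))
  ids <- sprintf("gene%05d", seq_len(nGenes))
  alpha <- stats::rlnorm(nGenes, meanLogAlpha, sdLogAlpha)
  delta <- stats::rlnorm(nGenes, log(log(2) / medianHalfLife), sdLogHalfLife)
  te <- stats::rlnorm(nGenes, meanLogTE, sdLogTE)
  nDirect <- floor(fracDirect * nGenes)
  nIndirect <- floor(fracIndirect * nGenes)
  cls <- rep("null", nGenes)
  pick <- sample.int(nGenes, nDirect + nIndirect)
  cls[pick[seq_len(nDirect)]] <- "direct_target"
  cls[pick[nDirect + seq_len(nIndirect)]] <- "indirect_transcriptional"
  tt <- DataFrame(gene_id = ids, alpha = alpha, delta = delta, te = te,
                  effect_class = cls,
                  dispersion = rep_len(dispersion, nGenes))
  for (g in genotypes) {
    am <- rep(1, nGenes); dm <- rep(1, nGenes); tm <- rep(1, nGenes)
    if (g != genotypes[1L]) {
      dm[cls == "direct_target"] <- directDeltaMult
      tm[cls == "direct_target"] <- directTeMult
      am[cls == "indirect_transcriptional"] <- indirectAlphaMult
    }
    tt[[paste0(g, "_alpha_mult")]] <- am
    tt[[paste0(g, "_delta_mult")]] <- dm
    tt[[paste0(g, "_te_mult")]] <- tm
  }
  bf <- matrix(2^stats::rnorm(nGenes * nBatches, 0, batchSdLog2),
               nGenes, nBatches,
               dimnames = list(ids, paste0("b", seq_len(nBatches))))
  new("KineticTruth", truth = tt, batchFactors = bf,
      genotypes = genotypes, seed = as.integer(seed))
}

# Default sample sheet for the three-fraction experiment: one replicate per
# genotype per batch (the emulated study design: two replicates, one per
# batch).
.fractionSampleSheet <- function(truth, nReps = 1L) {
  gt <- truth@genotypes
  batches <- colnames(truth@batchFactors)
  expand.grid(genotype = gt, batch = batches,
              replicate = seq_len(nReps), stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

# Expected steady-state abundance per gene for one genotype and batch.
.expectedAbundance <- function(truth, genotype, batch) {
  tt <- truth@truth
  am <- tt[[paste0(genotype, "_alpha_mult")]]
  dm <- tt[[paste0(genotype, "_delta_mult")]]
  (tt$alpha * am) / (tt$delta * dm) * truth@batchFactors[, batch]
}

#' Simulate three-fraction (total / newly-synthesised / pre-existing) counts
#'
#' Library means follow the steady-state labelling model: abundance
#' \code{A = alpha / delta} (genotype- and batch-adjusted), labelled share
#' \code{theta = 1 - exp(-delta * tLabel)}; the labelled fraction captures
#' \code{purity} of labelled molecules and the remainder leaks into the
#' unlabelled fraction. Expected labelled + pre-existing means equal the
#' total mean exactly before independent negative-binomial noise.
#'
#' @param truth a [KineticTruth-class] object.
#' @param design a [LabelingDesign-class] object; when its \code{depth} is
#'   set, each library is scaled so its expected size equals \code{depth},
#'   otherwise raw expected means times the per-fraction
#'   \code{fractionScale} are used.
#' @param samples data.frame with columns \code{genotype}, \code{batch},
#'   \code{replicate}; defaults to one replicate per genotype per batch.
#' @param seed integer seed.
#' @return Named list of three \code{SummarizedExperiment}s (\code{total},
#'   \code{new}, \code{pre}), sharing genes, with sample metadata in
#'   \code{colData} and the per-library expected means in the
#'   \code{mu} assay.
#' @export
simulateFractionCounts <- function(truth, design = labelingDesign(),
                                   samples = NULL, seed = 1) {
  stopIfNot(is(truth, "KineticTruth"), "truth must be KineticTruth")
  stopIfNot(is(design, "LabelingDesign"), "design must be LabelingDesign")
  if (is.null(samples)) samples <- .fractionSampleSheet(truth)
  need <- c("genotype", "batch", "replicate")
  stopIfNot(all(need %in% colnames(samples)),
            "samples needs genotype, batch, replicate")
  set.seed(subSeed(seed, "fractions"))
  tt <- truth@truth
  G <- nrow(tt)
  ids <- as.character(tt$gene_id)
  out <- list()
  for (fraction in c("total", "new", "pre")) {
    cnt <- matrix(0, G, nrow(samples))
    mu <- matrix(0, G, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      gt <- as.character(samples$genotype[j])
      b <- as.character(samples$batch[j])
      A <- .expectedAbundance(truth, gt, b)
      dm <- tt[[paste0(gt, "_delta_mult")]]
      theta <- 1 - exp(-(tt$delta * dm) * design@tLabel)
      m <- switch(fraction,
                  total = A,
                  new = A * theta * design@purity,
                  pre = A * (1 - theta) + A * theta * (1 - design@purity))
      m <- m * design@fractionScale[[fraction]]
      if (!is.na(design@depth)) m <- m * design@depth / sum(m)
      mu[, j] <- m
      cnt[, j] <- rnbinomMu(G, m, tt$dispersion)
    }
    cn <- sprintf("%s_%s_%s_r%s", fraction, samples$genotype,
                  samples$batch, samples$replicate)
    dimnames(cnt) <- list(ids, cn)
    dimnames(mu) <- list(ids, cn)
    cd <- S4Vectors::DataFrame(sample_id = cn, assay = fraction,
                               genotype = as.character(samples$genotype),
                               batch = as.character(samples$batch),
                               replicate = samples$replicate)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cnt, mu = mu), colData = cd)
    S4Vectors::metadata(se)$t_label <- design@tLabel
    out[[fraction]] <- se
  }
  out
}

#' Simulate ribosome-protected fragment counts
#'
#' Footprint means are proportional to genotype-adjusted abundance times
#' translation efficiency, so direct targets show an elevated knockout
#' footprint-to-abundance ratio.
#'
#' @param truth a [KineticTruth-class] object.
#' @param samples data.frame with \code{genotype}, \code{batch},
#'   \code{replicate}; defaults to two replicates per genotype in batch 1
#'   and three in batch 2 (the emulated five-replicate design).
#' @param depth expected reads per library (default 1e6).
#' @param seed integer seed.
#' @return A \code{SummarizedExperiment} of footprint counts with the
#'   expected means in the \code{mu} assay.
#' @export
simulateRiboCounts <- function(truth, samples = NULL, depth = 1e6, seed = 1) {
  stopIfNot(is(truth, "KineticTruth"), "truth must be KineticTruth")
  if (is.null(samples)) {
    batches <- colnames(truth@batchFactors)
    nr <- rep_len(c(2L, 3L), length(batches))
    samples <- do.call(rbind, lapply(seq_along(batches), function(bi) {
      expand.grid(genotype = truth@genotypes, batch = batches[bi],
                  replicate = seq_len(nr[bi]), stringsAsFactors = FALSE,
                  KEEP.OUT.ATTRS = FALSE)
    }))
  }
  set.seed(subSeed(seed, "ribo"))
  tt <- truth@truth
  G <- nrow(tt)
  cnt <- matrix(0, G, nrow(samples))
  mu <- matrix(0, G, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    gt <- as.character(samples$genotype[j])
    b <- as.character(samples$batch[j])
    A <- .expectedAbundance(truth, gt, b)
    m <- A * tt$te * tt[[paste0(gt, "_te_mult")]]
    if (!is.na(depth) && sum(m) > 0) m <- m * depth / sum(m)
    mu[, j] <- m
    cnt[, j] <- rnbinomMu(G, m, tt$dispersion)
  }
  cn <- sprintf("ribo_%s_%s_r%s", samples$genotype, samples$batch,
                samples$replicate)
  ids <- as.character(tt$gene_id)
  dimnames(cnt) <- list(ids, cn)
  dimnames(mu) <- list(ids, cn)
  cd <- S4Vectors::DataFrame(sample_id = cn, assay = "ribo",
                             genotype = as.character(samples$genotype),
                             batch = as.character(samples$batch),
                             replicate = samples$replicate)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, mu = mu), colData = cd)
}

#' Simulate five planted regulatory-mode archetypes
#'
#' Generates a genes x measures z-score matrix around five archetype
#' profiles (stability-dominant, stability+translation,
#' translation-dominant, transcription+translation,
#' transcription-dominant). The archetypes are five evenly spaced
#' directions in the plane of row-shape variation that the correlation
#' distance resolves (maximal mutual angular separation of 72 degrees),
#' with magnitude \code{scale} and a common offset; Gaussian noise of SD
#' \code{noiseSd} is added per entry. A correlated total-mRNA z column is
#' appended for reporting.
#'
#' @param nPerCluster genes per archetype (default 40).
#' @param noiseSd per-entry noise SD (default 0.3).
#' @param scale archetype magnitude in z units (default 1.8).
#' @param offset common z offset (default 0.8; the genes emulated are
#'   derepressed, so profiles sit above zero on average).
#' @param seed integer seed.
#' @return List with \code{z} (matrix with columns \code{new},
#'   \code{stability}, \code{ribo}, \code{total}; rownames are gene ids)
#'   and \code{cluster} (named integer vector of true archetype labels).
#' @export
simulateModeArchetypes <- function(nPerCluster = 40, noiseSd = 0.3,
                                   scale = 1.8, offset = 0.8, seed = 1) {
  u <- c(2, -1, -1) / sqrt(6)
  v <- c(0, 1, -1) / sqrt(2)
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  A <- t(vapply(ang, function(a) scale * (cos(a) * u + sin(a) * v) + offset,
                numeric(3)))
  colnames(A) <- c("new", "stability", "ribo")
  set.seed(subSeed(seed, "kinetics"))
  lab <- rep(seq_len(5L), each = nPerCluster)
  n <- length(lab)
  X <- A[lab, , drop = FALSE] +
    matrix(stats::rnorm(n * 3, 0, noiseSd), n, 3)
  total <- 0.5 * X[, "new"] + 0.4 * X[, "stability"] +
    stats::rnorm(n, 0, noiseSd)
  Z <- cbind(X, total = total)
  rownames(Z) <- sprintf("gene%05d", seq_len(n))
  list(z = Z, cluster = stats::setNames(lab, rownames(Z)))
}
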