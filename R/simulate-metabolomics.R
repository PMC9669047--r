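# Default LC-MS panel: 52 metabolites spanning glycolysis, the pentose
# phosphate pathway, the TCA cycle, amino acids and nucleotides, with
# planted knockout fold changes emulating the magnitudes the assays are
# designed to detect (glutamine strongly up, alpha-ketoglutarate
# three-fold, modest increases in PPP/methionine-cycle/TCA intermediates).
.defaultMetabolitePanel <- function() {
  fold <- c(
    "glucose-6-phosphate" = 1, "fructose-6-phosphate" = 1,
    "fructose-1,6-bisphosphate" = 1, "dihydroxyacetone-phosphate" = 1,
    "glyceraldehyde-3-phosphate" = 1, "3-phosphoglycerate" = 1,
    "phosphoenolpyruvate" = 1, "pyruvate" = 1, "lactate" = 1,
    "6-phosphogluconate" = 1.6, "ribose-5-phosphate" = 1.6,
    "sedoheptulose-7-phosphate" = 1.6, "erythrose-4-phosphate" = 1.2,
    "citrate" = 1.3, "isocitrate" = 1.3, "alpha-ketoglutarate" = 3,
    "succinate" = 1, "fumarate" = 1.2, "malate" = 1.3,
    "oxaloacetate" = 1, "2-hydroxyglutarate" = 1.5,
    "glutamine" = 8, "glutamate" = 1.4, "aspartate" = 1.2,
    "asparagine" = 1.1, "alanine" = 1, "serine" = 1.2, "glycine" = 1.1,
    "proline" = 1, "arginine" = 1, "lysine" = 1, "histidine" = 1,
    "threonine" = 1, "methionine" = 1.2, "cysteine" = 1, "valine" = 1,
    "leucine" = 1, "isoleucine" = 1, "phenylalanine" = 1,
    "tyrosine" = 1, "tryptophan" = 1,
    "S-adenosyl-methionine" = 1.5, "creatine" = 1, "taurine" = 1,
    "ATP" = 1, "ADP" = 1, "AMP" = 1.1, "NAD+" = 1, "NADH" = 1,
    "GTP" = 1, "UTP" = 1, "glutathione" = 1.2)
  stopifnot(length(fold) == 52L)
  fold
}

# Synthetic stand-ins for derivatised-fragment formulas (atom counts
# excluding the tracer carbon positions) and planted true MIDs for the
# GC-MS tracing spectra. Real fragment formulas are instrument- and
# derivatisation-specific user inputs; these defaults exist only so the
# correction can be exercised end-to-end.
.defaultSpectrumPanel <- function() {
  list(
    glutamate = list(formula = c(C = 12, H = 26, N = 1, O = 4, Si = 2),
                     n_tracer = 5,
                     true_mid = c(0.30, 0.02, 0.02, 0.03, 0.53, 0.10)),
    `alpha-ketoglutarate` = list(
      formula = c(C = 11, H = 21, O = 5, Si = 2), n_tracer = 5,
      true_mid = c(0.35, 0.02, 0.03, 0.05, 0.45, 0.10)),
    succinate = list(formula = c(C = 8, H = 19, O = 4, Si = 2),
                     n_tracer = 4,
                     true_mid = c(0.45, 0.03, 0.07, 0.05, 0.40)),
    malate = list(formula = c(C = 14, H = 31, O = 5, Si = 3), n_tracer = 4,
                  true_mid = c(0.50, 0.03, 0.07, 0.05, 0.35)),
    citrate = list(formula = c(C = 20, H = 45, O = 7, Si = 4), n_tracer = 6,
                   true_mid = c(0.55, 0.03, 0.05, 0.04, 0.28, 0.03, 0.02)),
    pyruvate = list(formula = c(C = 3, H = 8, N = 1, O = 2, Si = 1),
                    n_tracer = 3,
                    true_mid = c(0.60, 0.05, 0.05, 0.30)),
    lactate = list(formula = c(C = 9, H = 22, O = 3, Si = 2), n_tracer = 3,
                   true_mid = c(0.55, 0.05, 0.05, 0.35)),
    serine = list(formula = c(C = 13, H = 31, N = 1, O = 3, Si = 3),
                  n_tracer = 3,
                  true_mid = c(0.70, 0.05, 0.10, 0.15)))
}

#' Simulate an LC-MS metabolite table and GC-MS isotopologue spectra
#'
#' The metabolite table holds per-sample relative peak areas: log-normal
#' baselines, genotype fold changes planted per metabolite, multiplicative
#' log-normal measurement noise, and per-sample internal-standard and
#' total-ion-content rows (raw areas are baseline times the sample's
#' internal standard, so internal-standard normalisation recovers the
#' relative abundances). Isotopologue spectra are built by convolving a
#' planted true mass isotopomer distribution with the natural-abundance
#' matrix of a (synthetic stand-in) fragment formula, scaling to a total
#' ion count and applying multiplicative noise.
#'
#' @param seed integer seed.
#' @param nReps replicates per genotype (default 6, the emulated LC-MS
#'   design).
#' @param genotypes genotype levels (first is control).
#' @param folds named per-metabolite knockout fold changes; defaults to
#'   the built-in 52-metabolite panel.
#' @param noiseSdLog2 per-measurement multiplicative noise SD on the log2
#'   scale (default 0.15).
#' @param spectra spectrum definitions (metabolite, formula, n_tracer,
#'   true_mid); defaults to the built-in panel.
#' @param isoNoiseSdLog2 multiplicative noise on spectrum ion counts
#'   (default 0.02; set 0 for noiseless spectra).
#' @param isoTotalIons expected total ion count per spectrum
#'   (default 1e5).
#' @param bufferShifts extra measured mass shifts beyond M+n_tracer
#'   (default 3, capturing heavy-isotope tails).
#' @return List with \code{metabolites} (elements \code{table} raw areas,
#'   \code{internal_standard}, \code{tic}, \code{samples},
#'   \code{true_fold}) and \code{spectra} (list of spectrum lists, each
#'   with the planted \code{true_mid} retained for recovery tests).
#' @export
simulateMetabolomics <- function(seed = 1, nReps = 6,
                                 genotypes = c("control", "dKO"),
                                 folds = .defaultMetabolitePanel(),
                                 noiseSdLog2 = 0.15,
                                 spectra = .defaultSpectrumPanel(),
                                 isoNoiseSdLog2 = 0.02,
                                 isoTotalIons = 1e5,
                                 bufferShifts = 3L) {
  set.seed(subSeed(seed, "metabolomics"))
  M <- length(folds)
  mets <- names(folds)
  samples <- expand.grid(replicate = seq_len(nReps), genotype = genotypes,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sid <- sprintf("%s_r%d", samples$genotype, samples$replicate)
  base <- stats::rlnorm(M, 0, 1)
  rel <- matrix(0, M, nrow(samples), dimnames = list(mets, sid))
  for (j in seq_len(nrow(samples))) {
    f <- if (samples$genotype[j] == genotypes[1L]) 1 else folds
    rel[, j] <- base * f * 2^stats::rnorm(M, 0, noiseSdLog2)
  }
  is_ <- stats::rlnorm(nrow(samples), log(100), 0.1)
  raw <- sweep(rel, 2L, is_, "*")
  tic <- colSums(raw)
  metabolites <- list(
    table = raw,
    internal_standard = stats::setNames(is_, sid),
    tic = stats::setNames(tic, sid),
    samples = S4Vectors::DataFrame(sample_id = sid,
                                   genotype = samples$genotype,
                                   replicate = samples$replicate),
    true_fold = folds)

  out <- list()
  for (nm in names(spectra)) {
    sp <- spectra[[nm]]
    n <- sp$n_tracer
    stopIfNot(abs(sum(sp$true_mid) - 1) < 1e-8,
              paste("true MID must sum to 1 for", nm))
    nShifts <- n + 1L + bufferShifts
    C <- naturalAbundanceMatrix(sp$formula, n, nShifts = nShifts)
    mu <- as.numeric(C %*% sp$true_mid) * isoTotalIons
    noisy <- mu * 2^stats::rnorm(nShifts, 0, isoNoiseSdLog2)
    out[[nm]] <- list(metabolite = nm, formula = sp$formula,
                      n_tracer = n, raw_counts = noisy,
                      true_mid = sp$true_mid)
  }
  list(metabolites = metabolites, spectra = out)
}

#' Simulate a complete multiomic input bundle
#'
#' Convenience wrapper running every generator under sub-seeds of one
#' master seed and collecting the results (with ground truth) into a
#' [SyntheticBundle-class].
#'
#' @param nGenes number of genes.
#' @param seed master integer seed.
#' @param design a [LabelingDesign-class] for the fraction counts.
#' @param riboDepth expected reads per ribosome-profiling library.
#' @param ... passed to [simulateKinetics()].
#' @return A [SyntheticBundle-class] object.
#' @export
simulateBundle <- function(nGenes = 2000, seed = 1,
                           design = labelingDesign(depth = 1e6),
                           riboDepth = 1e6, ...) {
  truth <- simulateKinetics(nGenes, seed = seed, ...)
  counts <- simulateFractionCounts(truth, design = design, seed = seed)
  counts$ribo <- simulateRiboCounts(truth, depth = riboDepth, seed = seed)
  clip <- simulateUtrCrosslinks(truth, seed = seed)
  metab <- simulateMetabolomics(seed = seed)
  new("SyntheticBundle", counts = counts, utr = clip$utr,
      utrSeq = clip$utrSeq, crosslinks = clip$sites,
      metabolites = metab$metabolites, spectra = metab$spectra,
      truth = truth, seed = as.integer(seed))
}
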