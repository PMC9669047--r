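#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Ground-truth kinetic parameters for a simulated transcriptome
#'
#' Container for the per-gene synthesis rate (alpha, transcripts/h on an
#' arbitrary scale), first-order decay rate (delta, 1/h), translation
#' efficiency (TE, footprints per transcript), effect class and
#' genotype-specific multipliers used by the count simulators. Batch effects
#' are multiplicative log-normal factors on abundance, stored per gene and
#' batch.
#'
#' @slot truth A \linkS4class{DataFrame} with one row per gene and columns
#'   \code{gene_id}, \code{alpha}, \code{delta}, \code{te},
#'   \code{effect_class}, \code{dispersion} and per-genotype multiplier
#'   columns \code{<genotype>_alpha_mult}, \code{<genotype>_delta_mult},
#'   \code{<genotype>_te_mult}.
#' @slot batchFactors Numeric matrix (genes x batches) of multiplicative
#'   abundance factors.
#' @slot genotypes Character vector of genotype levels (first is the
#'   reference/control).
#' @slot seed Integer seed the object was generated with.
#'
#' @seealso [simulateKinetics()]
#' @export
setClass("KineticTruth",
  slots = c(
    truth = "DataFrame",
    batchFactors = "matrix",
    genotypes = "character",
    seed = "integer"
  )
)

setValidity("KineticTruth", function(object) {
  tt <- object@truth
  msg <- character()
  need <- c("gene_id", "alpha", "delta", "te", "effect_class", "dispersion")
  if (!all(need %in% colnames(tt)))
    msg <- c(msg, paste("truth must contain columns:", paste(need, collapse = ", ")))
  else {
    if (any(tt$alpha <= 0)) msg <- c(msg, "alpha must be > 0")
    if (any(tt$delta <= 0)) msg <- c(msg, "delta must be > 0")
    if (any(tt$te < 0)) msg <- c(msg, "te must be >= 0")
    if (any(tt$dispersion < 0)) msg <- c(msg, "dispersion must be >= 0")
    if (anyDuplicated(tt$gene_id)) msg <- c(msg, "gene_id must be unique")
  }
  if (nrow(object@batchFactors) != nrow(tt))
    msg <- c(msg, "batchFactors must have one row per gene")
  if (length(msg)) msg else TRUE
})

#' Labelling-experiment design
#'
#' Describes the 4sU pulse and the library-scaling structure of a simulated
#' three-fraction experiment.
#'
#' @slot tLabel Labelling duration in hours.
#' @slot fractionScale Named numeric of per-fraction global scale factors
#'   applied to the expected counts of the \code{total}, \code{new} and
#'   \code{pre} libraries. These emulate the unknown capture/normalisation
#'   scales that the correction-factor regression recovers.
#' @slot purity Fraction of labelled molecules captured in the labelled
#'   fraction; the remainder leaks into the unlabelled fraction.
#' @slot depth Target expected library size per fraction library, or
#'   \code{NA_real_} to use the raw expected means.
#'
#' @seealso [labelingDesign()], [simulateFractionCounts()]
#' @export
setClass("LabelingDesign",
  slots = c(
    tLabel = "numeric",
    fractionScale = "numeric",
    purity = "numeric",
    depth = "numeric"
  )
)

setValidity("LabelingDesign", function(object) {
  msg <- character()
  if (length(object@tLabel) != 1L || object@tLabel <= 0)
    msg <- c(msg, "tLabel must be a single value > 0")
  fs <- object@fractionScale
  if (!all(c("total", "new", "pre") %in% names(fs)) || any(fs <= 0))
    msg <- c(msg, "fractionScale must be positive and named total/new/pre")
  if (object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be in (0, 1]")
  if (!is.na(object@depth) && object@depth <= 0)
    msg <- c(msg, "depth must be > 0 (or NA)")
  if (length(msg)) msg else TRUE
})

#' Constructor for a [LabelingDesign-class] object
#'
#' @param tLabel labelling duration in hours (default 1, the final hour of
#'   activation used in the emulated experiment).
#' @param fractionScale named per-fraction global scale factors (see class
#'   documentation).
#' @param purity labelled-fraction separation purity in (0, 1].
#' @param depth expected reads per library, or \code{NA} for raw scale.
#' @return A [LabelingDesign-class] object.
#' @examples
#' labelingDesign(tLabel = 1, depth = 1e6)
#' @export
labelingDesign <- function(tLabel = 1,
                           fractionScale = c(total = 1, new = 1, pre = 1),
                           purity = 1,
                           depth = NA_real_) {
  new("LabelingDesign", tLabel = as.numeric(tLabel),
      fractionScale = fractionScale, purity = as.numeric(purity),
      depth = as.numeric(depth))
}

#' Per-sample correction factors for fraction-to-total scaling
#'
#' Result of regressing normalised total counts on the labelled and
#' unlabelled fraction counts without intercept, one regression per sample
#' pair. The mean factors are used downstream to reconstruct the labelled
#' share of each transcript pool.
#'
#' @slot samples DataFrame with columns \code{sample}, \code{cL}, \code{cU},
#'   \code{valid}, \code{r2}, \code{n_genes}.
#' @slot meanCL,meanCU Means of the factors across valid samples.
#'
#' @seealso [estimateCorrectionFactors()]
#' @export
setClass("CorrectionFactors",
  slots = c(samples = "DataFrame", meanCL = "numeric", meanCU = "numeric")
)

#' Regulatory-mode clustering of derepressed genes
#'
#' @slot zMatrix Numeric matrix (genes x measures) of z-scores, with columns
#'   \code{new}, \code{stability}, \code{ribo} and (reporting only)
#'   \code{total}.
#' @slot cluster Named integer vector of cluster assignments in 1..k.
#' @slot tree The \code{hclust} object (complete linkage on 1 - Pearson
#'   correlation between rows).
#' @slot summary DataFrame of per-cluster median z per measure with
#'   categorical labels.
#' @slot excluded Character vector of gene ids dropped because their
#'   clustering-measure profile was constant (correlation undefined).
#'
#' @seealso [clusterModes()], [summarizeClusters()]
#' @export
setClass("RegulatoryModes",
  slots = c(
    zMatrix = "matrix",
    cluster = "integer",
    tree = "ANY",
    summary = "DataFrame",
    excluded = "character"
  )
)

setValidity("RegulatoryModes", function(object) {
  if (length(object@cluster) != nrow(object@zMatrix))
    return("every clustered gene needs an assignment")
  TRUE
})

#' CLIP 3'UTR target set for one dataset
#'
#' @slot dataset Dataset label.
#' @slot targets Character vector of target gene ids.
#' @slot summary DataFrame with per-gene 3'UTR crosslink read sums and the
#'   90th-percentile-normalised log2 summary score (detected genes only).
#'
#' @seealso [callTargetsIclip()], [callTargetsHitsclip()],
#'   [summarizeCrosslinks()]
#' @export
setClass("ClipTargets",
  slots = c(dataset = "character", targets = "character", summary = "DataFrame")
)

#' Expression- and 3'UTR-length-matched control gene sets
#'
#' @slot focal Character vector of focal gene ids.
#' @slot sets List of control sets (character vectors), each the same size as
#'   the focal set and disjoint from it.
#' @slot matching DataFrame recording, per focal gene, the size of the
#'   length-eligible candidate pool.
#' @slot seed Integer seed used for the resampling.
#'
#' @seealso [buildMatchedControls()]
#' @export
setClass("MatchedControlSets",
  slots = c(
    focal = "character",
    sets = "list",
    matching = "DataFrame",
    seed = "integer"
  )
)

setValidity("MatchedControlSets", function(object) {
  n <- length(object@focal)
  bad <- vapply(object@sets, function(s) {
    length(s) != n || anyDuplicated(s) > 0L || any(s %in% object@focal)
  }, logical(1))
  if (any(bad))
    return("each control set must match the focal size, contain no duplicates and exclude focal genes")
  TRUE
})

#' Corrected mass isotopomer distribution for one spectrum
#'
#' @slot metabolite Metabolite label.
#' @slot mid Numeric vector of length n_tracer + 1; non-negative, sums to 1.
#' @slot fractionalLabelling Average labelled fraction of tracer positions,
#'   in [0, 1].
#' @slot totalRelativeIons Total (internal-standard-normalised) ion counts of
#'   the raw spectrum.
#'
#' @seealso [correctMID()]
#' @export
setClass("MIDResult",
  slots = c(
    metabolite = "character",
    mid = "numeric",
    fractionalLabelling = "numeric",
    totalRelativeIons = "numeric"
  )
)

setValidity("MIDResult", function(object) {
  msg <- character()
  if (any(object@mid < -1e-9)) msg <- c(msg, "mid entries must be >= 0")
  if (abs(sum(object@mid) - 1) > 1e-6) msg <- c(msg, "mid must sum to 1")
  fl <- object@fractionalLabelling
  if (fl < -1e-9 || fl > 1 + 1e-9) msg <- c(msg, "fractional labelling must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Bundle of simulated multiomic inputs with ground truth
#'
#' Everything the pipeline consumes, generated under a single seed:
#' count matrices for the four assays, the 3'UTR annotation and sequences,
#' crosslink-site tables, the LC-MS metabolite table and the GC-MS
#' isotopologue spectra, plus the kinetic ground truth.
#'
#' @slot counts Named list of \code{SummarizedExperiment}s
#'   (\code{total}, \code{new}, \code{pre}, \code{ribo}).
#' @slot utr \code{GRanges} of 3'UTRs (names and \code{gene_id} metadata).
#' @slot utrSeq \code{DNAStringSet} of 3'UTR sequences keyed by gene id.
#' @slot crosslinks Named list of crosslink-site \code{data.frame}s (one per
#'   dataset/replicate) with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{read_count}, \code{strand}, \code{fdr}.
#' @slot metabolites List with elements \code{table} (metabolite x sample
#'   relative areas), \code{internal_standard}, \code{tic}, \code{samples}
#'   (metadata DataFrame) and \code{true_fold} (named planted folds).
#' @slot spectra List of isotopologue spectra, each a list with
#'   \code{metabolite}, \code{formula}, \code{n_tracer}, \code{raw_counts}
#'   and the planted \code{true_mid}.
#' @slot truth The [KineticTruth-class] object.
#' @slot seed Integer master seed.
#'
#' @seealso [simulateBundle()]
#' @export
setClass("SyntheticBundle",
  slots = c(
    counts = "list",
    utr = "ANY",
    utrSeq = "ANY",
    crosslinks = "list",
    metabolites = "list",
    spectra = "list",
    truth = "KineticTruth",
    seed = "integer"
  )
)
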