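#' @rdname KineticTruth-class
#' @export
setMethod("truthTable", "KineticTruth", function(x) x@truth)

#' @rdname KineticTruth-class
#' @export
setMethod("geneIds", "KineticTruth", function(x) as.character(x@truth$gene_id))

#' @rdname KineticTruth-class
#' @export
setMethod("show", "KineticTruth", function(object) {
  tt <- object@truth
  cat("KineticTruth with", nrow(tt), "genes,",
      ncol(object@batchFactors), "batches\n")
  cat("  genotypes:", paste(object@genotypes, collapse = ", "), "\n")
  cls <- table(tt$effect_class)
  cat("  effect classes:",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  cat("  median half-life:",
      signif(stats::median(log(2) / tt$delta), 3), "h\n")
})

#' @rdname CorrectionFactors-class
#' @export
setMethod("sampleFactors", "CorrectionFactors", function(x) x@samples)

#' @rdname CorrectionFactors-class
#' @export
setMethod("meanFactors", "CorrectionFactors",
          function(x) c(cL = x@meanCL, cU = x@meanCU))

#' @rdname CorrectionFactors-class
#' @param object An object.
#' @export
setMethod("show", "CorrectionFactors", function(object) {
  cat("CorrectionFactors over", nrow(object@samples), "sample pairs\n")
  cat(sprintf("  mean cL = %.4f, mean cU = %.4f\n",
              object@meanCL, object@meanCU))
  if (any(!object@samples$valid))
    cat("  invalid samples:",
        paste(object@samples$sample[!object@samples$valid], collapse = ", "),
        "\n")
})

#' @rdname RegulatoryModes-class
#' @export
setMethod("clusterAssignments", "RegulatoryModes", function(x) x@cluster)

#' @rdname RegulatoryModes-class
#' @export
setMethod("clusterSummary", "RegulatoryModes", function(x) x@summary)

#' @rdname RegulatoryModes-class
#' @export
setMethod("modeZMatrix", "RegulatoryModes", function(x) x@zMatrix)

#' @rdname RegulatoryModes-class
#' @param object An object.
#' @export
setMethod("show", "RegulatoryModes", function(object) {
  k <- length(unique(object@cluster))
  cat("RegulatoryModes:", length(object@cluster), "genes in", k, "clusters\n")
  print(table(cluster = object@cluster))
  if (length(object@excluded))
    cat("  excluded (constant profile):", length(object@excluded), "genes\n")
})

#' @rdname ClipTargets-class
#' @export
setMethod("targetGenes", "ClipTargets", function(x) x@targets)

#' @rdname ClipTargets-class
#' @export
setMethod("summaryScores", "ClipTargets", function(x) x@summary)

#' @rdname ClipTargets-class
#' @param object An object.
#' @export
setMethod("show", "ClipTargets", function(object) {
  cat("ClipTargets [", object@dataset, "]: ", length(object@targets),
      " target genes; summary scores for ", nrow(object@summary),
      " detected genes\n", sep = "")
})

#' @rdname MatchedControlSets-class
#' @export
setMethod("controlSets", "MatchedControlSets", function(x) x@sets)

#' @rdname MatchedControlSets-class
#' @export
setMethod("focalSet", "MatchedControlSets", function(x) x@focal)

#' @rdname MatchedControlSets-class
#' @param object An object.
#' @export
setMethod("show", "MatchedControlSets", function(object) {
  cat("MatchedControlSets:", length(object@sets), "control sets of",
      length(object@focal), "genes (seed", object@seed, ")\n")
})

#' @rdname MIDResult-class
#' @importFrom IRanges mid
#' @export mid
#' @exportMethod mid
#' @export
setMethod("mid", "MIDResult", function(x) x@mid)

#' @rdname MIDResult-class
#' @export
setMethod("fractionalLabelling", "MIDResult", function(x) x@fractionalLabelling)

#' @rdname MIDResult-class
#' @param object An object.
#' @export
setMethod("show", "MIDResult", function(object) {
  cat("MIDResult [", object@metabolite, "]\n", sep = "")
  cat("  MID:", paste(sprintf("M+%d=%.4f", seq_along(object@mid) - 1L,
                              object@mid), collapse = " "), "\n")
  cat(sprintf("  fractional labelling: %.4f\n", object@fractionalLabelling))
})
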