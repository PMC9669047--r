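#' @rdname KineticTruth-class
#' @param object,x An object.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname KineticTruth-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname CorrectionFactors-class
#' @param x An object.
#' @export
setGeneric("sampleFactors", function(x) standardGeneric("sampleFactors"))

#' @rdname CorrectionFactors-class
#' @export
setGeneric("meanFactors", function(x) standardGeneric("meanFactors"))

#' @rdname RegulatoryModes-class
#' @param x An object.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname RegulatoryModes-class
#' @export
setGeneric("clusterSummary", function(x) standardGeneric("clusterSummary"))

#' @rdname RegulatoryModes-class
#' @export
setGeneric("modeZMatrix", function(x) standardGeneric("modeZMatrix"))

#' @rdname ClipTargets-class
#' @param x An object.
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname ClipTargets-class
#' @export
setGeneric("summaryScores", function(x) standardGeneric("summaryScores"))

#' @rdname MatchedControlSets-class
#' @param x An object.
#' @export
setGeneric("controlSets", function(x) standardGeneric("controlSets"))

#' @rdname MatchedControlSets-class
#' @export
setGeneric("focalSet", function(x) standardGeneric("focalSet"))

#' @rdname MIDResult-class
#' @param x An object.
#' @export
setGeneric("fractionalLabelling", function(x) standardGeneric("fractionalLabelling"))
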