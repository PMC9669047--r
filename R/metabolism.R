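#' Natural-abundance correction matrix for an isotopologue spectrum
#'
#' Builds the matrix \code{C} with \code{C[i+1, j+1]} the probability that a
#' molecule carrying \code{j} tracer labels is measured at mass shift
#' \code{i}. Each column is the convolution of the independent heavy-isotope
#' contributions of all non-tracer atoms of the measured fragment with, by
#' default, the natural \eqn{^{13}}C binomial of the \code{nTracer - j}
#' unlabelled tracer positions. The matrix is lower-triangular in the sense
#' \code{C[i, j] = 0} for \code{i < j}: labels cannot lower the mass.
#'
#' @param formula named numeric vector of atom counts of the measured
#'   fragment, excluding the tracer carbon positions; names among
#'   \code{C, H, N, O, Si, S}.
#' @param nTracer number of carbon positions that can carry tracer label
#'   (>= 1).
#' @param nShifts number of measured mass shifts (rows); default
#'   \code{nTracer + 1}.
#' @param abundances isotope frequency table, see [isotopeAbundances()].
#' @param natural13CAtTracer include natural \eqn{^{13}}C at the unlabelled
#'   tracer positions (full correction, default TRUE).
#' @return \code{nShifts x (nTracer + 1)} matrix of probabilities; column
#'   sums are at most 1 (equal to 1 when \code{nShifts} spans all heavy
#'   combinations).
#' @export
naturalAbundanceMatrix <- function(formula, nTracer, nShifts = nTracer + 1L,
                                   abundances = isotopeAbundances(),
                                   natural13CAtTracer = TRUE) {
  stopIfNot(nTracer >= 1, "nTracer must be >= 1")
  stopIfNot(all(formula >= 0), "negative atom counts")
  stopIfNot(all(names(formula) %in% names(abundances)),
            "formula elements must be among the abundance table's")
  base <- 1
  for (el in names(formula)) {
    n <- as.integer(formula[[el]])
    if (n > 0)
      base <- .convShift(base, .convPower(abundances[[el]], n, nShifts),
                         nShifts)
  }
  C <- matrix(0, nrow = nShifts, ncol = nTracer + 1L)
  for (j in 0:nTracer) {
    dist <- base
    nUnlab <- nTracer - j
    if (natural13CAtTracer && nUnlab > 0)
      dist <- .convShift(dist, .convPower(abundances$C, nUnlab, nShifts),
                         nShifts)
    idx <- j + seq_along(dist)
    idx <- idx[idx <= nShifts]
    C[idx, j + 1L] <- dist[seq_along(idx)]
  }
  C
}

#' Correct a raw isotopologue spectrum to a mass isotopomer distribution
#'
#' Solves \code{measured = C \%*\% m} for the true label distribution
#' \code{m} by non-negative least squares, renormalises \code{m} to sum to
#' one, and derives the fractional labelling
#' \code{FL = sum(j * m_j) / nTracer}.
#'
#' @param spectrum list with elements \code{metabolite}, \code{formula}
#'   (named atom counts, non-tracer), \code{n_tracer} and \code{raw_counts}
#'   (ion counts at shifts M+0 upward).
#' @param matrix optional precomputed correction matrix; built from the
#'   spectrum's formula when \code{NULL}.
#' @param abundances,natural13CAtTracer passed to
#'   [naturalAbundanceMatrix()] when the matrix is built here.
#' @return A [MIDResult-class] object.
#' @export
correctMID <- function(spectrum, matrix = NULL,
                       abundances = isotopeAbundances(),
                       natural13CAtTracer = TRUE) {
  stopIfNot(all(c("n_tracer", "raw_counts") %in% names(spectrum)),
            "spectrum needs n_tracer and raw_counts")
  y <- as.numeric(spectrum$raw_counts)
  stopIfNot(all(y >= 0), "ion counts must be >= 0")
  stopIfNot(sum(y) > 0, "all-zero spectrum")
  n <- as.integer(spectrum$n_tracer)
  if (is.null(matrix))
    matrix <- naturalAbundanceMatrix(spectrum$formula, n,
                                     nShifts = length(y),
                                     abundances = abundances,
                                     natural13CAtTracer = natural13CAtTracer)
  stopIfNot(nrow(matrix) == length(y) && ncol(matrix) == n + 1L,
            "matrix dimensions inconsistent with spectrum")
  # solve on the unit-sum spectrum: the solver's convergence tolerance is
  # absolute, and the MID is renormalised below regardless of scale
  m <- pracma::lsqnonneg(matrix, y / sum(y))$x
  stopIfNot(sum(m) > 0, "correction produced an all-zero solution")
  midv <- m / sum(m)
  fl <- sum((0:n) * midv) / n
  new("MIDResult",
      metabolite = if (!is.null(spectrum$metabolite))
        as.character(spectrum$metabolite) else NA_character_,
      mid = midv, fractionalLabelling = fl, totalRelativeIons = sum(y))
}

#' Tabulate corrected MIDs for a list of spectra
#'
#' @param spectra list of spectra as accepted by [correctMID()].
#' @param ... passed to [correctMID()].
#' @return \linkS4class{DataFrame} with \code{metabolite}, \code{n_tracer},
#'   \code{M0..Mk} (padded with NA beyond each metabolite's range),
#'   \code{fractional_labelling}, \code{total_relative_ions}.
#' @export
correctSpectra <- function(spectra, ...) {
  res <- lapply(spectra, correctMID, ...)
  kmax <- max(vapply(res, function(r) length(r@mid), integer(1)))
  out <- DataFrame(
    metabolite = vapply(res, function(r) r@metabolite, character(1)),
    n_tracer = vapply(res, function(r) length(r@mid) - 1L, integer(1)))
  for (i in seq_len(kmax)) {
    out[[paste0("M", i - 1L)]] <- vapply(res, function(r)
      if (length(r@mid) >= i) r@mid[i] else NA_real_, numeric(1))
  }
  out$fractional_labelling <- vapply(res, function(r) r@fractionalLabelling,
                                     numeric(1))
  out$total_relative_ions <- vapply(res, function(r) r@totalRelativeIons,
                                    numeric(1))
  out
}

#' Partition relative ion counts into labelled and unlabelled components
#'
#' Labelled abundance is the total relative ion count times the fractional
#' labelling; unlabelled is the complement.
#'
#' @param total total relative ion counts (>= 0).
#' @param fl fractional labelling in [0, 1], recycled against \code{total}.
#' @return \linkS4class{DataFrame} with \code{labelled}, \code{unlabelled}.
#' @examples
#' labelledUnlabelledSplit(100, 0.25)   # 25 / 75
#' @export
labelledUnlabelledSplit <- function(total, fl) {
  stopIfNot(all(fl >= 0 & fl <= 1), "fractional labelling outside [0, 1]")
  stopIfNot(all(total >= 0), "total must be >= 0")
  DataFrame(labelled = total * fl, unlabelled = total * (1 - fl))
}

#' Normalise a metabolite abundance table
#'
#' Divides raw peak areas by the per-sample internal-standard signal and,
#' when requested, additionally by the per-sample total ion content.
#'
#' @param raw metabolite x sample matrix of peak areas.
#' @param internalStandard per-sample internal-standard signal (> 0).
#' @param tic per-sample total ion content (> 0; required for
#'   \code{mode = "is_tic"}).
#' @param mode one of \code{"is"} (internal standard only),
#'   \code{"is_tic"} (both) or \code{"raw"}.
#' @return Normalised matrix with a \code{"normalisation"} attribute
#'   recording the provenance.
#' @export
normalizeMetabolites <- function(raw, internalStandard, tic = NULL,
                                 mode = c("is", "is_tic", "raw")) {
  mode <- match.arg(mode)
  raw <- as.matrix(raw)
  stopIfNot(all(raw >= 0), "abundances must be >= 0")
  out <- raw
  if (mode != "raw") {
    stopIfNot(length(internalStandard) == ncol(raw),
              "need an internal-standard value per sample")
    stopIfNot(all(internalStandard > 0), "zero internal standard")
    out <- sweep(out, 2L, internalStandard, "/")
    if (mode == "is_tic") {
      stopIfNot(!is.null(tic) && length(tic) == ncol(raw),
                "need a TIC value per sample")
      stopIfNot(all(tic > 0), "zero total ion content")
      out <- sweep(out, 2L, tic, "/")
    }
  }
  attr(out, "normalisation") <- switch(mode, raw = "raw",
                                       is = "IS-normalised",
                                       is_tic = "IS+TIC-normalised")
  out
}

#' Per-metabolite genotype comparison
#'
#' Fold change of genotype means and an unpaired two-sided Student's t-test
#' (equal variance) per metabolite, with Benjamini-Hochberg adjustment
#' across metabolites.
#'
#' @param table metabolite x sample matrix of (normalised) abundances.
#' @param genotype per-sample genotype labels.
#' @param contrast length-2 character (numerator, denominator), default
#'   \code{c("dKO", "control")}.
#' @return \linkS4class{DataFrame} with \code{metabolite}, \code{fold},
#'   \code{t}, \code{p}, \code{fdr}.
#' @export
metaboliteStats <- function(table, genotype, contrast = c("dKO", "control")) {
  table <- as.matrix(table)
  stopIfNot(length(genotype) == ncol(table), "need a genotype per sample")
  stopIfNot(all(contrast %in% genotype), "both genotypes must be present")
  sel1 <- genotype == contrast[1L]
  sel2 <- genotype == contrast[2L]
  stopIfNot(sum(sel1) >= 2 && sum(sel2) >= 2,
            "need >= 2 samples per genotype")
  ids <- rownames(table)
  if (is.null(ids)) ids <- sprintf("m%d", seq_len(nrow(table)))
  stat <- t(apply(table, 1L, function(row) {
    x <- row[sel1]; y <- row[sel2]
    scale <- max(abs(mean(x)), abs(mean(y)), .Machine$double.eps)
    if (stats::sd(x) < 1e-10 * scale && stats::sd(y) < 1e-10 * scale) {
      # degenerate variance: identical groups are a non-effect, separated
      # constant groups an infinitely confident one
      if (mean(x) == mean(y)) return(c(mean(x) / mean(y), 0, 1))
      return(c(mean(x) / mean(y), sign(mean(x) - mean(y)) * Inf, 0))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    c(mean(x) / mean(y), unname(tt$statistic), tt$p.value)
  }))
  DataFrame(metabolite = ids, fold = unname(stat[, 1L]),
            t = unname(stat[, 2L]), p = unname(stat[, 3L]),
            fdr = unname(stats::p.adjust(stat[, 3L], method = "BH")))
}

#' Per-sample ratio between two metabolites
#'
#' Element-wise per-sample ratio (not a ratio of means), e.g.
#' alpha-ketoglutarate to succinate.
#'
#' @param table metabolite x sample matrix.
#' @param numerator,denominator metabolite row names.
#' @return Named numeric vector of per-sample ratios.
#' @export
ratioPairs <- function(table, numerator, denominator) {
  table <- as.matrix(table)
  stopIfNot(all(c(numerator, denominator) %in% rownames(table)),
            "both metabolites must be present")
  den <- table[denominator, ]
  stopIfNot(all(den > 0), "zero denominator")
  table[numerator, ] / den
}

#' Row-wise log2 deviation from the row mean
#'
#' @param mat numeric matrix with positive row means.
#' @param floor optional positive floor applied to the entries before
#'   taking logs (guards zero entries).
#' @return Matrix of \code{log2(x / rowMean)} values.
#' @examples
#' rowLog2Deviation(matrix(c(2, 8), 1))   # log2(0.4), log2(1.6)
#' @export
rowLog2Deviation <- function(mat, floor = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(floor)) {
    stopIfNot(floor > 0, "floor must be > 0")
    mat[mat < floor] <- floor
  }
  stopIfNot(all(mat > 0), "non-positive entries; supply a floor")
  sweep(log2(mat), 1L, log2(rowMeans(mat)), "-")
}
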