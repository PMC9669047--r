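#' Build expression- and 3'UTR-length-matched control gene sets
#'
#' For each gene in the focal set, a matched control is drawn from the
#' remaining unassigned genes (not focal, not already chosen within the
#' current control set) by three nested rules: (1) keep candidates whose
#' 3'UTR length differs from the focal gene's by less than 25% (relative to
#' the focal length), or, if fewer than 1000 qualify, the 1000 with the
#' closest length; (2) of these, keep the 100 closest in expression
#' (log2 FPKM); (3) draw one uniformly at random. Repeating this for every
#' focal gene yields one control set of equal size; \code{nSets} sets are
#' drawn (controls may recur across sets but not within one).
#' Ties at the length or expression cutoffs are broken by gene id.
#'
#' @param focal character vector of focal gene ids.
#' @param expr named per-gene expression (log2-transformed FPKM) covering
#'   the whole universe.
#' @param utrLen named per-gene 3'UTR length in nt, same coverage.
#' @param nSets number of control sets (default 100).
#' @param seed integer seed for the resampling.
#' @param lengthTol relative length tolerance (default 0.25).
#' @param lengthPool fallback pool size for rule 1 (default 1000).
#' @param exprPool pool size for rule 2 (default 100).
#' @return A [MatchedControlSets-class] object.
#' @export
buildMatchedControls <- function(focal, expr, utrLen, nSets = 100, seed = 1,
                                 lengthTol = 0.25, lengthPool = 1000,
                                 exprPool = 100) {
  universe <- names(expr)
  stopIfNot(!is.null(universe) && !is.null(names(utrLen)),
            "expr and utrLen must be named by gene id")
  stopIfNot(all(focal %in% universe), "expr must cover all focal genes")
  stopIfNot(all(universe %in% names(utrLen)),
            "utrLen must cover the whole universe")
  utrLen <- utrLen[universe]
  nF <- length(focal)
  nU <- length(universe)
  stopIfNot(nU - nF >= nF,
            "candidate pool exhausted: universe too small for the focal set")
  isFocal <- universe %in% focal
  idRank <- rank(universe, ties.method = "first")
  candIdx <- which(!isFocal)

  # per focal gene: candidates ordered by (|length diff|, id) and by
  # (|expr diff|, id); membership of the strict <25% band
  fIdx <- match(focal, universe)
  ordLen <- vector("list", nF)
  ordExpr <- vector("list", nF)
  nBand <- integer(nF)
  inBand <- vector("list", nF)
  for (i in seq_len(nF)) {
    dLen <- abs(utrLen[candIdx] - utrLen[fIdx[i]])
    dExpr <- abs(expr[candIdx] - expr[fIdx[i]])
    ordLen[[i]] <- candIdx[order(dLen, idRank[candIdx])]
    ordExpr[[i]] <- candIdx[order(dExpr, idRank[candIdx])]
    band <- candIdx[dLen / utrLen[fIdx[i]] < lengthTol]
    nBand[i] <- length(band)
    inBand[[i]] <- band
  }

  set.seed(seed)
  sets <- vector("list", nSets)
  used <- logical(nU)
  for (s in seq_len(nSets)) {
    used[] <- FALSE
    pick <- integer(nF)
    for (i in seq_len(nF)) {
      if (nBand[i] >= lengthPool) {
        elig <- inBand[[i]][!used[inBand[[i]]]]
      } else {
        ol <- ordLen[[i]]
        elig <- ol[!used[ol]]
        if (length(elig) > lengthPool) elig <- elig[seq_len(lengthPool)]
      }
      stopIfNot(length(elig) > 0, "candidate pool exhausted")
      eligMask <- logical(nU)
      eligMask[elig] <- TRUE
      oe <- ordExpr[[i]]
      pool <- oe[eligMask[oe]]
      if (length(pool) > exprPool) pool <- pool[seq_len(exprPool)]
      pick[i] <- pool[sample.int(length(pool), 1L)]
      used[pick[i]] <- TRUE
    }
    sets[[s]] <- universe[pick]
  }
  new("MatchedControlSets", focal = as.character(focal), sets = sets,
      matching = DataFrame(gene_id = focal, n_length_eligible = nBand),
      seed = as.integer(seed))
}

#' Enrichment of a gene-level predicate against matched controls
#'
#' Counts how many focal genes satisfy a predicate (is a CLIP target /
#' carries an ARE motif), repeats the count in each matched control set,
#' and reports the observed count normalised to the control median together
#' with the 5th/95th percentiles of the (median-normalised) control counts
#' as a confidence band.
#'
#' @param controls a [MatchedControlSets-class] object.
#' @param predicate named logical vector defined for every focal and
#'   control gene.
#' @param name label for the predicate.
#' @return \linkS4class{DataFrame} (one row) with \code{predicate},
#'   \code{observed}, \code{control_median}, \code{normalized},
#'   \code{q05_norm}, \code{q95_norm}; the raw per-set counts are attached
#'   as \code{metadata()$control_counts}. If the control median is 0,
#'   \code{normalized} and the band are \code{NA} and the absolute counts
#'   remain available.
#' @export
enrichmentVsControls <- function(controls, predicate, name = "predicate") {
  stopIfNot(is(controls, "MatchedControlSets"),
            "controls must be MatchedControlSets")
  allGenes <- unique(c(controls@focal, unlist(controls@sets)))
  stopIfNot(all(allGenes %in% names(predicate)),
            "predicate must cover every focal and control gene")
  obs <- sum(predicate[controls@focal])
  cc <- vapply(controls@sets, function(s) sum(predicate[s]), numeric(1))
  med <- stats::median(cc)
  if (med > 0) {
    qq <- stats::quantile(cc, c(0.05, 0.95), type = 7)
    res <- DataFrame(predicate = name, observed = obs, control_median = med,
                     normalized = obs / med,
                     q05_norm = unname(qq[1]) / med,
                     q95_norm = unname(qq[2]) / med)
  } else {
    res <- DataFrame(predicate = name, observed = obs, control_median = med,
                     normalized = NA_real_, q05_norm = NA_real_,
                     q95_norm = NA_real_)
  }
  metadata(res)$control_counts <- cc
  res
}

#' Compare z-scores between rate-limiting and other genes
#'
#' Per assay, an unpaired two-sided Student's t-test (equal variance)
#' between the genes annotated as rate-limiting and the rest, with
#' Benjamini-Hochberg correction across assays.
#'
#' @param zTable genes x assays numeric matrix (rownames = gene ids).
#' @param rateLimiting named logical vector flagging rate-limiting genes.
#' @return \linkS4class{DataFrame} with \code{assay}, \code{n_rl},
#'   \code{n_other}, \code{mean_rl}, \code{mean_other}, \code{t}, \code{p},
#'   \code{fdr}.
#' @export
compareRateLimiting <- function(zTable, rateLimiting) {
  zTable <- as.matrix(zTable)
  stopIfNot(!is.null(rownames(zTable)), "zTable needs gene ids as rownames")
  stopIfNot(all(rownames(zTable) %in% names(rateLimiting)),
            "rateLimiting must cover every gene in zTable")
  rl <- rateLimiting[rownames(zTable)]
  stopIfNot(sum(rl) >= 2 && sum(!rl) >= 2,
            "both groups need at least two members")
  out <- NULL
  for (a in colnames(zTable)) {
    x <- zTable[rl, a]; y <- zTable[!rl, a]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    out <- rbind(out, DataFrame(assay = a, n_rl = length(x),
                                n_other = length(y), mean_rl = mean(x),
                                mean_other = mean(y),
                                t = unname(tt$statistic),
                                p = tt$p.value))
  }
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
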