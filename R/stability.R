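#' Estimate fraction-to-total correction factors
#'
#' The labelled (newly-synthesised) and unlabelled (pre-existing) fractions
#' of a 4sU experiment are sequenced as separate libraries, so their
#' normalised counts sit on unknown scales relative to the total-RNA
#' library. Because every transcript molecule is either labelled or not,
#' the total obeys the mixture identity \code{T = cL * L + cU * U} for some
#' per-sample pair of positive factors. These are recovered by ordinary
#' least squares of the normalised total counts on the two fraction counts,
#' without intercept, over genes above a minimum-expression floor; the
#' factors are then averaged across samples for half-life estimation.
#'
#' With counting noise, naive per-sample least squares is attenuated: the
#' regressors L and U are themselves noisy counts, strongly collinear
#' through gene abundance, so errors-in-variables bias is severe. The
#' default estimator therefore solves the weighted moment (instrumental-
#' variable) equations in which both the instruments and the inverse-
#' square-total weights come from the mean of the \emph{other} samples,
#' whose noise is independent of the sample being fitted. On noiseless
#' data the identity is exact and both methods return the exact factors;
#' with a single sample the plain least-squares fit is the only option.
#'
#' @param total,new,pre normalised count matrices (genes x samples) for the
#'   three fractions, sharing the gene index; columns are matched by
#'   position (sample pairing across fractions).
#' @param minTotal eligibility floor on normalised total counts
#'   (default 10).
#' @param minGenes minimum number of eligible genes per sample (default 50).
#' @param method \code{"iv"} (default; cross-sample-weighted moment
#'   estimator) or \code{"ols"} (plain no-intercept least squares).
#' @return A [CorrectionFactors-class] object. Samples with a singular
#'   design or a non-positive fitted coefficient are flagged invalid and
#'   excluded from the means.
#' @examples
#' A <- matrix(runif(200, 20, 200), 100)
#' th <- matrix(runif(200, 0.1, 0.9), 100)
#' L <- A * th; U <- A * (1 - th)
#' cf <- estimateCorrectionFactors(2 * L + 0.5 * U, L, U)
#' meanFactors(cf)   # (2, 0.5) exactly
#' @export
estimateCorrectionFactors <- function(total, new, pre,
                                      minTotal = 10, minGenes = 50,
                                      method = c("iv", "ols")) {
  method <- match.arg(method)
  total <- as.matrix(total); new <- as.matrix(new); pre <- as.matrix(pre)
  stopIfNot(all(dim(total) == dim(new)) && all(dim(total) == dim(pre)),
            "the three fraction matrices must share genes and samples")
  ns <- ncol(total)
  ids <- colnames(total)
  if (is.null(ids)) ids <- sprintf("sample%d", seq_len(ns))
  res <- DataFrame(sample = ids, cL = NA_real_, cU = NA_real_,
                   valid = FALSE, r2 = NA_real_, n_genes = NA_integer_)
  for (j in seq_len(ns)) {
    eligible <- total[, j] >= minTotal
    n <- sum(eligible)
    res$n_genes[j] <- n
    if (n < minGenes) next
    Tj <- total[eligible, j]; Lj <- new[eligible, j]; Uj <- pre[eligible, j]
    X <- cbind(L = Lj, U = Uj)
    if (method == "iv" && ns > 1L) {
      Lo <- rowMeans(new[eligible, -j, drop = FALSE])
      Uo <- rowMeans(pre[eligible, -j, drop = FALSE])
      To <- rowMeans(total[eligible, -j, drop = FALSE])
      Z <- cbind(L = Lo, U = Uo) / pmax(To, minTotal)^2
      co <- tryCatch(drop(solve(crossprod(Z, X), crossprod(Z, Tj))),
                     error = function(e) c(L = NA_real_, U = NA_real_))
      resid <- Tj - X %*% ifelse(is.finite(co), co, 0)
    } else {
      fit <- tryCatch(stats::lm.fit(X, Tj), error = function(e) NULL)
      if (is.null(fit) || fit$rank < 2L) next
      co <- fit$coefficients
      resid <- fit$residuals
    }
    if (!all(is.finite(co))) next
    res$cL[j] <- co[["L"]]; res$cU[j] <- co[["U"]]
    res$r2[j] <- 1 - sum(resid^2) / sum((Tj - mean(Tj))^2)
    res$valid[j] <- all(co > 0)
  }
  if (!any(res$valid))
    stop("no sample yielded valid positive correction factors", call. = FALSE)
  new("CorrectionFactors", samples = res,
      meanCL = mean(res$cL[res$valid]), meanCU = mean(res$cU[res$valid]))
}

#' Estimate per-gene mRNA half-lives from fraction counts
#'
#' Under first-order decay at steady state, a pulse of length \code{t}
#' labels the share \code{theta = 1 - exp(-delta * t)} of each transcript
#' pool. The labelled share is reconstructed per gene from group-mean
#' normalised fraction counts rescaled by the mean correction factors:
#' \code{theta = cL*L / (cL*L + cU*U)}. The reconstructed total
#' (denominator) guarantees \code{theta} in (0, 1) whenever both components
#' are positive. Then \code{delta = -log(1 - theta) / t} and
#' \code{t1/2 = log(2) / delta}.
#'
#' @param new,pre normalised count matrices (genes x samples); columns
#'   matched by position.
#' @param factors a [CorrectionFactors-class] object.
#' @param grouping per-sample grouping labels (e.g. genotype, or
#'   genotype:batch); half-lives are estimated on group-mean counts.
#' @param tLabel labelling duration in hours (default 1).
#' @param minCount group-mean reconstructed total below this flags the row
#'   invalid with reason \code{low_counts} (default 10).
#' @return \linkS4class{DataFrame} with columns \code{gene_id},
#'   \code{group}, \code{theta}, \code{delta}, \code{half_life},
#'   \code{valid}, \code{reason} (one of \code{ok}, \code{theta<=0},
#'   \code{theta>=1}, \code{low_counts}).
#' @export
estimateHalfLives <- function(new, pre, factors, grouping,
                              tLabel = 1, minCount = 10) {
  stopIfNot(tLabel > 0, "tLabel must be > 0")
  stopIfNot(is(factors, "CorrectionFactors"), "factors must be CorrectionFactors")
  new <- as.matrix(new); pre <- as.matrix(pre)
  stopIfNot(all(dim(new) == dim(pre)), "new and pre must share dimensions")
  stopIfNot(length(grouping) == ncol(new), "need a group label per sample")
  ids <- rownames(new)
  if (is.null(ids)) ids <- sprintf("g%0*d", nchar(nrow(new)), seq_len(nrow(new)))
  cL <- factors@meanCL; cU <- factors@meanCU
  out <- NULL
  for (grp in unique(as.character(grouping))) {
    sel <- as.character(grouping) == grp
    L <- unname(rowMeans(new[, sel, drop = FALSE]))
    U <- unname(rowMeans(pre[, sel, drop = FALSE]))
    recon <- cL * L + cU * U
    theta <- ifelse(recon > 0, cL * L / recon, NA_real_)
    reason <- rep("ok", length(theta))
    reason[!is.na(theta) & theta <= 0] <- "theta<=0"
    reason[!is.na(theta) & theta >= 1] <- "theta>=1"
    reason[is.na(theta) | recon < minCount] <- "low_counts"
    valid <- reason == "ok"
    delta <- ifelse(valid, -log(1 - theta) / tLabel, NA_real_)
    out <- rbind(out, DataFrame(
      gene_id = ids, group = grp, theta = theta, delta = delta,
      half_life = log(2) / delta, valid = valid, reason = reason))
  }
  out
}

#' Batch-standardised log2 change in mRNA stability
#'
#' For each batch, the log2 fold change in half-life between the two
#' genotypes is computed over genes with valid half-lives in both, then
#' divided by that batch's standard deviation of the changes; the final
#' score is the mean of the standardised values over the batches in which a
#' gene is valid. Standardising per batch before averaging absorbs the
#' batch-to-batch differences in the spread of the stability estimates.
#'
#' @param halflives output of [estimateHalfLives()] where \code{group} was
#'   formed as \code{genotype.batch} (see \code{sep}).
#' @param contrast length-2 character (numerator, denominator genotype),
#'   default \code{c("dKO", "control")}.
#' @param sep separator between genotype and batch in \code{group}
#'   (default \code{"."}).
#' @return \linkS4class{DataFrame} with \code{gene_id}, per-batch
#'   standardised changes \code{z_<batch>}, \code{n_batches} and
#'   \code{score}. Genes valid in no batch are dropped.
#' @export
standardizedStabilityChange <- function(halflives,
                                        contrast = c("dKO", "control"),
                                        sep = ".") {
  grp <- as.character(halflives$group)
  parts <- strsplit(grp, sep, fixed = TRUE)
  stopIfNot(all(lengths(parts) == 2L),
            "group labels must be genotype<sep>batch")
  genotype <- vapply(parts, `[[`, character(1), 1L)
  batch <- vapply(parts, `[[`, character(1), 2L)
  stopIfNot(all(contrast %in% genotype),
            "both contrast genotypes must be present")
  batches <- sort(unique(batch))
  ids <- sort(unique(as.character(halflives$gene_id)))
  zmat <- matrix(NA_real_, length(ids), length(batches),
                 dimnames = list(ids, batches))
  for (b in batches) {
    hNum <- halflives[genotype == contrast[1L] & batch == b, ]
    hDen <- halflives[genotype == contrast[2L] & batch == b, ]
    num <- structure(hNum$half_life, names = as.character(hNum$gene_id))
    den <- structure(hDen$half_life, names = as.character(hDen$gene_id))
    vNum <- structure(hNum$valid, names = as.character(hNum$gene_id))
    vDen <- structure(hDen$valid, names = as.character(hDen$gene_id))
    common <- intersect(names(num)[vNum], names(den)[vDen])
    if (length(common) < 2L)
      stop("need at least two genes valid in both genotypes in batch ", b,
           call. = FALSE)
    d <- log2(num[common] / den[common])
    s <- stats::sd(d)
    stopIfNot(s > 0, paste0("zero within-batch SD in batch ", b))
    zmat[common, b] <- d / s
  }
  nb <- rowSums(!is.na(zmat))
  keep <- nb > 0
  score <- rowMeans(zmat, na.rm = TRUE)
  res <- DataFrame(gene_id = ids[keep], n_batches = unname(nb[keep]),
                   score = unname(score[keep]))
  for (b in batches) res[[paste0("z_", b)]] <- unname(zmat[keep, b])
  res
}

#' Significance of stability changes via the expression-local z statistic
#'
#' Delegates to [intensityDiff()]: the stability score itself carries no
#' expression information, so the expression axis is supplied explicitly as
#' the mean normalised read counts across the total and newly-synthesised
#' libraries from which stability was estimated.
#'
#' @param change output of [standardizedStabilityChange()].
#' @param meanExpr named per-gene mean normalised counts (total + new
#'   libraries); must cover all genes in \code{change}.
#' @param windowFraction,minWindow passed to [intensityDiff()].
#' @param log2Expr should the expression axis be log2(x + 0.5) transformed
#'   before windowing (default TRUE)?
#' @return \code{change} with columns \code{expression}, \code{z}, \code{p},
#'   \code{fdr} appended.
#' @export
stabilitySignificance <- function(change, meanExpr, windowFraction = 0.01,
                                  minWindow = 200, log2Expr = TRUE) {
  ids <- as.character(change$gene_id)
  stopIfNot(all(ids %in% names(meanExpr)),
            "meanExpr must cover every gene in change")
  expr <- meanExpr[ids]
  ex <- if (log2Expr) log2(expr + 0.5) else expr
  names(ex) <- ids
  idf <- intensityDiff(ex, change$score, windowFraction = windowFraction,
                       minWindow = minWindow)
  change$expression <- as.numeric(expr)
  change$z <- idf$z
  change$p <- idf$p
  change$fdr <- idf$fdr
  change
}
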