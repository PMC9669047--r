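# Plain-text readers/writers for the pipeline's external file contracts:
# counts TSV (first column gene_id), sample sheet TSV, BED6 3'UTRs
# (0-based half-open), FASTA 3'UTR sequences, crosslink BED6+1 with a
# trailing fdr column, metabolite CSV (internal_standard / tic rows) and
# isotopologue CSV.

#' Write / read a counts matrix as TSV
#'
#' Rows are genes, columns samples, first column \code{gene_id}.
#'
#' @param counts matrix or \code{SummarizedExperiment} (first assay used).
#' @param path file path.
#' @return \code{readCountsTSV} returns a numeric matrix with gene
#'   rownames.
#' @export
writeCountsTSV <- function(counts, path) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, 1L)
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a sample sheet as TSV
#'
#' Columns \code{sample_id}, \code{assay}, \code{genotype}, \code{batch},
#' \code{replicate}.
#'
#' @param samples data.frame/DataFrame of sample metadata.
#' @param path file path.
#' @export
writeSampleSheet <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(batch = "character"))
}

#' Write / read 3'UTR annotation as BED6
#'
#' BED uses 0-based half-open coordinates; the name field carries the gene
#' id and the score field the feature length.
#'
#' @param utr \code{GRanges} with a \code{gene_id} metadata column.
#' @param path file path.
#' @return \code{readUtrBed} returns a \code{GRanges} with \code{gene_id},
#'   \code{feature} (\code{"3UTR"}) and \code{length} metadata.
#' @export
writeUtrBed <- function(utr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(utr)),
    start = GenomicRanges::start(utr) - 1L,
    end = GenomicRanges::end(utr),
    name = S4Vectors::mcols(utr)$gene_id,
    score = GenomicRanges::width(utr),
    strand = as.character(GenomicRanges::strand(utr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeUtrBed
#' @export
readUtrBed <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end),
                strand = df$strand)
  names(gr) <- df$name
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = df$name, feature = "3UTR", length = df$end - df$start)
  gr
}

#' Write / read 3'UTR sequences as FASTA
#'
#' @param seqs \code{DNAStringSet} (or named character) keyed by gene id.
#' @param path file path.
#' @export
writeUtrFasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeUtrFasta
#' @export
readUtrFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write / read crosslink sites as BED6+1
#'
#' Single-nucleotide intervals in 0-based half-open coordinates; the name
#' field is \code{dataset:replicate}, the score field the read count, and
#' a seventh column carries the per-site FDR.
#'
#' @param sites data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{read_count}, \code{strand},
#'   \code{fdr}.
#' @param path file path.
#' @export
writeCrosslinkBed <- function(sites, path) {
  df <- sites[, c("chrom", "start", "end", "name", "read_count", "strand",
                  "fdr")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCrosslinkBed
#' @export
readCrosslinkBed <- function(path) {
  utils::read.delim(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "read_count", "strand", "fdr"))
}

#' Read per-base conservation scores from bedGraph
#'
#' @param path bedGraph file (\code{chrom}, \code{start}, \code{end},
#'   \code{score}; 0-based half-open).
#' @return data.frame of the four columns.
#' @export
readBedGraph <- function(path) {
  utils::read.delim(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "score"))
}

# formula <-> string ("C12H26NO4Si2")
.formulaToString <- function(formula) {
  formula <- formula[formula > 0]
  paste0(names(formula), ifelse(formula == 1, "", formula), collapse = "")
}

.parseFormula <- function(s) {
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  counts <- ifelse(n == "", 1L, as.integer(n))
  stats::setNames(as.numeric(counts), el)
}

#' Write / read the metabolite table as CSV
#'
#' Rows are metabolites plus \code{internal_standard} and \code{tic} rows;
#' columns are samples.
#'
#' @param metabolites list as produced by [simulateMetabolomics()]
#'   (\code{table}, \code{internal_standard}, \code{tic}).
#' @param path file path.
#' @return \code{readMetaboliteCSV} returns that same list shape (without
#'   sample metadata).
#' @export
writeMetaboliteCSV <- function(metabolites, path) {
  tab <- rbind(metabolites$table,
               internal_standard = metabolites$internal_standard,
               tic = metabolites$tic)
  df <- data.frame(metabolite = rownames(tab), tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeMetaboliteCSV
#' @export
readMetaboliteCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  special <- c("internal_standard", "tic")
  list(table = m[!rownames(m) %in% special, , drop = FALSE],
       internal_standard = m["internal_standard", ],
       tic = m["tic", ])
}

#' Write / read isotopologue spectra as CSV
#'
#' Columns \code{metabolite}, \code{fragment_formula},
#' \code{n_tracer_carbons}, then \code{M0..Mk} ion counts (ragged rows
#' padded with empty cells).
#'
#' @param spectra list of spectra (see [simulateMetabolomics()]).
#' @param path file path.
#' @return \code{readIsotopologueCSV} returns the list-of-spectra shape
#'   accepted by [correctMID()].
#' @export
writeIsotopologueCSV <- function(spectra, path) {
  kmax <- max(vapply(spectra, function(s) length(s$raw_counts), integer(1)))
  rows <- lapply(spectra, function(s) {
    counts <- c(s$raw_counts, rep(NA_real_, kmax - length(s$raw_counts)))
    c(metabolite = s$metabolite,
      fragment_formula = .formulaToString(s$formula),
      n_tracer_carbons = s$n_tracer,
      stats::setNames(as.list(counts), paste0("M", seq_len(kmax) - 1L)))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeIsotopologueCSV
#' @export
readIsotopologueCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mcols <- grep("^M[0-9]+$", colnames(df), value = TRUE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    counts <- as.numeric(df[i, mcols])
    counts <- counts[!is.na(counts)]
    out[[as.character(df$metabolite[i])]] <- list(
      metabolite = as.character(df$metabolite[i]),
      formula = .parseFormula(as.character(df$fragment_formula[i])),
      n_tracer = as.integer(df$n_tracer_carbons[i]),
      raw_counts = counts)
  }
  out
}

#' Write every component of a synthetic bundle to a directory
#'
#' Emits the per-assay counts TSVs, the combined sample sheet, the 3'UTR
#' BED and FASTA, one crosslink BED per dataset:replicate, the metabolite
#' CSV and the isotopologue CSV.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  sheets <- list()
  for (a in names(bundle@counts)) {
    p <- file.path(dir, paste0("counts_", a, ".tsv"))
    writeCountsTSV(bundle@counts[[a]], p)
    paths[paste0("counts_", a)] <- p
    sheets[[a]] <- as.data.frame(
      SummarizedExperiment::colData(bundle@counts[[a]]))
  }
  p <- file.path(dir, "samples.tsv")
  writeSampleSheet(do.call(rbind, sheets), p)
  paths["samples"] <- p
  paths["utr_bed"] <- writeUtrBed(bundle@utr, file.path(dir, "utr.bed"))
  paths["utr_fasta"] <- writeUtrFasta(bundle@utrSeq,
                                      file.path(dir, "utr.fa"))
  for (nm in names(bundle@crosslinks)) {
    fn <- paste0("sites_", gsub(":", "_", nm), ".bed")
    paths[paste0("sites_", nm)] <-
      writeCrosslinkBed(bundle@crosslinks[[nm]], file.path(dir, fn))
  }
  paths["metabolites"] <- writeMetaboliteCSV(bundle@metabolites,
                                             file.path(dir, "metabolites.csv"))
  paths["spectra"] <- writeIsotopologueCSV(bundle@spectra,
                                           file.path(dir, "isotopologues.csv"))
  invisible(paths)
}
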