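#' Write a synthetic study to disk as plain-text files
#'
#' Emits genes.tsv, peaks.tsv, peaks.fasta, expression.csv, trace.csv,
#' cohort.csv, sets.gmt and truth.json into `dir`. All tables round-trip
#' through the package's own readers.
#'
#' @param study list from [simulateRegulomeStudy()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(study$genes, p("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$peaks, p("peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(study$sequences, p("peaks.fasta"))
  expr <- as.data.frame(SummarizedExperiment::assay(study$expression, "log2"))
  expr <- cbind(gene_id = rownames(expr), expr)
  utils::write.csv(expr, p("expression.csv"), row.names = FALSE)
  utils::write.csv(study$trace, p("trace.csv"), row.names = FALSE)
  utils::write.csv(study$cohort, p("cohort.csv"), row.names = FALSE)
  writeGMT(study$gene_sets, p("sets.gmt"))
  truth <- study$truth
  jsonlite::write_json(
    list(repressed_genes = truth@repressed,
         activated_genes = truth@activated,
         motif_peak_ids = truth@motif_peaks,
         decoy_no_motif = truth@decoy_no_motif,
         decoy_no_fold = truth@decoy_no_fold,
         decoy_no_expr = truth@decoy_no_expr,
         enriched_term = truth@enriched_term,
         true_period_h = truth@true_period_h),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Readers for the study's tabular formats
#'
#' `readGenesTable` and `readPeaksTable` read the tab-delimited annotation and
#' peak tables; `readTrace` and `readCohort` the CSV trace and patient tables;
#' `readExpressionMatrix` rebuilds the [SummarizedExperiment::SummarizedExperiment]
#' from expression.csv (column names `<condition>_<replicate>`);
#' `readGroundTruth` rebuilds the [GroundTruth-class] from truth.json.
#'
#' @param path file to read.
#' @return the corresponding object; see Details.
#' @export
readGenesTable <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "symbol", "chrom", "strand", "start", "end")
                %in% names(g)))
  g
}

#' @rdname readGenesTable
#' @export
readPeaksTable <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "start", "end", "conc_q", "conc_a")
                %in% names(p)))
  p
}

#' @rdname readGenesTable
#' @export
readTrace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_h", "value") %in% names(tr)))
  tr
}

#' @rdname readGenesTable
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readGenesTable
#' @export
readExpressionMatrix <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  cond <- sub("_[0-9]+$", "", colnames(m))
  repl <- as.integer(sub("^.*_", "", colnames(m)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = m),
    colData = S4Vectors::DataFrame(condition = cond, replicate = repl,
                                   row.names = colnames(m)))
}

#' @rdname readGenesTable
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_chr <- function(v) if (length(v)) as.character(v) else character(0)
  new("GroundTruth",
      repressed = as_chr(x$repressed_genes),
      activated = as_chr(x$activated_genes),
      motif_peaks = as_chr(x$motif_peak_ids),
      decoy_no_motif = as_chr(x$decoy_no_motif),
      decoy_no_fold = as_chr(x$decoy_no_fold),
      decoy_no_expr = as_chr(x$decoy_no_expr),
      enriched_term = x$enriched_term,
      true_period_h = x$true_period_h)
}

#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: term id, description, then member gene ids. The
#' in-memory form is a named list of character vectors with a `descriptions`
#' attribute (named character, parallel to the list).
#'
#' @param path GMT file.
#' @param sets named list of character vectors, optionally carrying a
#'   `descriptions` attribute.
#' @return `readGMT` returns the list form; `writeGMT` returns `path`
#'   invisibly.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, character(1), 2L), names(sets))
  sets
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
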