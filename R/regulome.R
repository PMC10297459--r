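#' Select condition-biased (differentially accessible) peaks
#'
#' A peak is open-in-qHSC when its pseudocounted concentration ratio
#' `(conc_q + pc) / (conc_a + pc)` strictly exceeds `fold`, and open-in-aHSC
#' symmetrically; ratios at exactly the threshold fall in neither set. The
#' pseudocount guards zero concentrations of count-derived signal; with
#' `pseudocount = 0`, non-positive concentrations are a validation error.
#'
#' @param peaks peak data.frame (`id`, `chrom`, `start`, `end`, `conc_q`,
#'   `conc_a`).
#' @param fold ratio threshold (strict >), default 2.
#' @param pseudocount added to both concentrations before the ratio
#'   (default 0.5).
#' @return list with character id vectors `q_open`, `a_open` and the named
#'   numeric `ratio` used.
#' @examples
#' pk <- data.frame(id = "p1", chrom = "chr1", start = 0L, end = 500L,
#'                  conc_q = 10, conc_a = 4)
#' differentialPeaks(pk)$q_open
#' @export
differentialPeaks <- function(peaks, fold = 2, pseudocount = 0.5) {
  stopifnot(all(c("id", "conc_q", "conc_a") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) {
    stop("peak intervals must satisfy start < end", call. = FALSE)
  }
  if (pseudocount == 0 && any(peaks$conc_q <= 0 | peaks$conc_a <= 0)) {
    stop("non-positive concentrations require a pseudocount", call. = FALSE)
  }
  ratio <- (peaks$conc_q + pseudocount) / (peaks$conc_a + pseudocount)
  names(ratio) <- peaks$id
  list(q_open = peaks$id[ratio > fold],
       a_open = peaks$id[ratio < 1 / fold],
       ratio = ratio)
}

.nearest_one <- function(p_start, p_end, tss, gene_ids) {
  # distance from each TSS to the 0-based half-open interval [p_start, p_end)
  d <- ifelse(tss >= p_start & tss < p_end, 0L,
              ifelse(tss < p_start, p_start - tss, tss - (p_end - 1L)))
  dmin <- min(d)
  cand <- gene_ids[d == dmin]
  # stated tie-break: lexicographically smaller gene id
  c(gene = sort(cand)[1L], dist = dmin)
}

#' Assign each peak to its nearest gene by TSS distance
#'
#' Distance is the minimum absolute separation between a gene's TSS and the
#' peak interval (0 when the TSS falls inside the peak); genes on other
#' chromosomes never match. Equidistant genes are broken by lexicographically
#' smaller gene id. Peaks on a chromosome with no genes get an explicit NA
#' assignment.
#'
#' @param peaks peak data.frame.
#' @param genes gene annotation data.frame.
#' @return data.frame with columns `peak_id`, `gene_id` (NA when no gene
#'   shares the chromosome), `distance_bp`.
#' @export
nearestGene <- function(peaks, genes) {
  tss_all <- tssOf(genes)
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  out_gene <- character(nrow(peaks))
  out_dist <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    idx <- by_chrom[[peaks$chrom[i]]]
    if (is.null(idx) || length(idx) == 0L) {
      out_gene[i] <- NA_character_
      next
    }
    r <- .nearest_one(peaks$start[i], peaks$end[i], tss_all[idx],
                      genes$gene_id[idx])
    out_gene[i] <- r[["gene"]]
    out_dist[i] <- as.integer(r[["dist"]])
  }
  data.frame(peak_id = peaks$id, gene_id = out_gene,
             distance_bp = out_dist, stringsAsFactors = FALSE)
}

#' Infer the CLOCK regulome from accessibility, motif and expression evidence
#'
#' The integration pipeline: (1) select condition-biased peaks
#' (ratio > `acc_fold`); (2) keep only motif-bearing peaks; (3) assign each
#' to its nearest gene; (4) look the gene up in the matching mutant-vs-WT
#' contrast (quiescent contrast for open-in-qHSC peaks, activated-state
#' contrast for open-in-aHSC peaks); (5) genes up more than `expr_fold` in
#' the mutant become `repressed` calls (the wild-type protein is modelled to
#' repress them), genes down more than `expr_fold` become `activated`; genes
#' failing both are dropped. One call is emitted per gene, backed by its
#' smallest-distance qualifying peak.
#'
#' @param peaks peak data.frame.
#' @param genes gene annotation data.frame.
#' @param has_motif either a named logical vector over all peak ids (as from
#'   [peakHasMotif()]) or a character vector of motif-bearing peak ids.
#' @param contrast_q Mut-Q vs WT-Q contrast data.frame (used for qHSC-open
#'   peaks).
#' @param contrast_a mutant-vs-WT contrast in the activated state (T0 by
#'   default in [standardContrasts()]; used for aHSC-open peaks). May be NULL
#'   if no aHSC-open peaks survive the filters.
#' @param acc_fold accessibility ratio threshold (strict >), default 2.
#' @param expr_fold expression fold threshold (strict >), default 1.5; the
#'   2-fold variant is available by argument.
#' @param p_max optional p-value gate on the expression contrast (default
#'   NULL: fold only).
#' @param pseudocount concentration pseudocount for [differentialPeaks()].
#' @return data.frame with columns `gene_id`, `mode` (repressed/activated),
#'   `peak_id`, `peak_state` (open-in-qHSC/open-in-aHSC), `expression_fold`
#'   (signed linear ratio, mutant vs WT), `log2fc`, `p`, `distance_bp`,
#'   sorted by `gene_id`.
#' @export
inferRegulome <- function(peaks, genes, has_motif, contrast_q,
                          contrast_a = NULL, acc_fold = 2, expr_fold = 1.5,
                          p_max = NULL, pseudocount = 0.5) {
  if (is.character(has_motif)) {
    orphan <- setdiff(has_motif, peaks$id)
    if (length(orphan)) {
      stop("motif peak ids absent from the peak table: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    has_motif <- stats::setNames(peaks$id %in% has_motif, peaks$id)
  } else {
    orphan <- setdiff(peaks$id, names(has_motif))
    if (length(orphan)) {
      stop("peaks with no motif flag: ", paste(orphan, collapse = ", "),
           call. = FALSE)
    }
  }
  dp <- differentialPeaks(peaks, fold = acc_fold, pseudocount = pseudocount)
  branches <- list(
    list(ids = dp$q_open, state = "open-in-qHSC", contrast = contrast_q),
    list(ids = dp$a_open, state = "open-in-aHSC", contrast = contrast_a)
  )
  calls <- list()
  for (br in branches) {
    ids <- br$ids[has_motif[br$ids]]
    if (!length(ids)) next
    if (is.null(br$contrast)) {
      stop("peaks are ", br$state, " but no matching expression contrast ",
           "was supplied", call. = FALSE)
    }
    ctr <- br$contrast
    nn <- nearestGene(peaks[match(ids, peaks$id), , drop = FALSE], genes)
    nn <- nn[!is.na(nn$gene_id), , drop = FALSE]
    orphan <- setdiff(nn$gene_id, ctr$gene_id)
    if (length(orphan)) {
      stop("nearest genes absent from the expression contrast: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    m <- match(nn$gene_id, ctr$gene_id)
    l2fc <- ctr$log2fc[m]
    pval <- ctr$p[m]
    up <- 2^l2fc > expr_fold
    dn <- 2^(-l2fc) > expr_fold
    if (!is.null(p_max)) {
      ok <- !is.na(pval) & pval < p_max
      up <- up & ok
      dn <- dn & ok
    }
    keep <- up | dn
    if (!any(keep)) next
    calls[[br$state]] <- data.frame(
      gene_id = nn$gene_id[keep],
      mode = ifelse(up[keep], "repressed", "activated"),
      peak_id = nn$peak_id[keep],
      peak_state = br$state,
      expression_fold = ifelse(l2fc[keep] >= 0, 2^l2fc[keep],
                               -(2^(-l2fc[keep]))),
      log2fc = l2fc[keep],
      p = pval[keep],
      distance_bp = nn$distance_bp[keep],
      stringsAsFactors = FALSE
    )
  }
  if (!length(calls)) {
    return(data.frame(gene_id = character(0), mode = character(0),
                      peak_id = character(0), peak_state = character(0),
                      expression_fold = numeric(0), log2fc = numeric(0),
                      p = numeric(0), distance_bp = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, calls)
  # one call per gene: best-supported peak = smallest TSS distance,
  # then smaller peak id for determinism
  res <- res[order(res$gene_id, res$distance_bp, res$peak_id), , drop = FALSE]
  res <- res[!duplicated(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
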