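.assay_cols <- function(se, condition) {
  which(SummarizedExperiment::colData(se)$condition == condition)
}

#' Pairwise contrast between two expression conditions
#'
#' For every gene, the log2 fold-change is the difference of replicate means
#' (positive means higher in `cond_a`), the p-value comes from a
#' pooled-variance two-sample t-test on the log2 replicates, and FDR is
#' Benjamini-Hochberg across all genes in the contrast. With a single
#' replicate on either side the fold-change is still returned but p and FDR
#' are flagged unavailable (NA).
#'
#' The signed `fold_change` column follows the microarray convention:
#' `2^log2fc` when up, `-2^(-log2fc)` when down, so its magnitude is always
#' the linear ratio in the direction of change.
#'
#' @param se [SummarizedExperiment::SummarizedExperiment] with assay `log2`
#'   and colData column `condition`.
#' @param cond_a,cond_b condition labels; positive log2fc means higher in
#'   `cond_a`.
#' @return data.frame with columns `gene_id`, `comparison`, `log2fc`,
#'   `fold_change`, `p`, `fdr`.
#' @examples
#' study <- simulateRegulomeStudy(simulationConfig(seed = 1, n_genes = 60,
#'                                                 n_peaks = 80))
#' head(expressionContrast(study$expression, "Mut-Q", "WT-Q"))
#' @export
expressionContrast <- function(se, cond_a, cond_b) {
  conds <- SummarizedExperiment::colData(se)$condition
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% conds) {
      stop("unknown condition label: '", cc, "' (available: ",
           paste(unique(conds), collapse = ", "), ")", call. = FALSE)
    }
  }
  m <- SummarizedExperiment::assay(se, "log2")
  if (is.null(rownames(m))) {
    stop("expression matrix must carry gene ids as rownames", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("expression values must be finite", call. = FALSE)
  a <- m[, .assay_cols(se, cond_a), drop = FALSE]
  b <- m[, .assay_cols(se, cond_b), drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  l2fc <- rowMeans(a) - rowMeans(b)
  if (na >= 2L && nb >= 2L) {
    va <- apply(a, 1L, stats::var)
    vb <- apply(b, 1L, stats::var)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se_d <- sqrt(sp2 * (1 / na + 1 / nb))
    tt <- l2fc / se_d
    p <- 2 * stats::pt(-abs(tt), df = na + nb - 2)
    # degenerate zero-variance genes: identical replicates
    p[se_d == 0 & l2fc == 0] <- 1
    p[se_d == 0 & l2fc != 0] <- 0
    fdr <- stats::p.adjust(p, method = "BH")
  } else {
    p <- rep(NA_real_, length(l2fc))
    fdr <- p
  }
  data.frame(
    gene_id = rownames(m),
    comparison = paste(cond_a, "vs", cond_b),
    log2fc = unname(l2fc),
    fold_change = ifelse(l2fc >= 0, 2^l2fc, -(2^(-l2fc))),
    p = unname(p),
    fdr = unname(fdr),
    stringsAsFactors = FALSE
  )
}

#' The five standard contrasts used by clustering and regulome inference
#'
#' Mutant effect in quiescence (Mut-Q vs WT-Q), the four activation responses
#' (each genotype's activated conditions at T0 and T12 against its quiescent
#' state), and the mutant effect in the activated state at both timepoints.
#'
#' @param se expression [SummarizedExperiment::SummarizedExperiment].
#' @return named list of contrast data.frames: `mut_q`, `wt_act_t0`,
#'   `wt_act_t12`, `mut_act_t0`, `mut_act_t12`, `mut_a_t0`, `mut_a_t12`.
#' @export
standardContrasts <- function(se) {
  list(
    mut_q = expressionContrast(se, "Mut-Q", "WT-Q"),
    wt_act_t0 = expressionContrast(se, "WT-A-T0", "WT-Q"),
    wt_act_t12 = expressionContrast(se, "WT-A-T12", "WT-Q"),
    mut_act_t0 = expressionContrast(se, "Mut-A-T0", "Mut-Q"),
    mut_act_t12 = expressionContrast(se, "Mut-A-T12", "Mut-Q"),
    mut_a_t0 = expressionContrast(se, "Mut-A-T0", "WT-A-T0"),
    mut_a_t12 = expressionContrast(se, "Mut-A-T12", "WT-A-T12")
  )
}

.direction <- function(contrast, fold, p_max) {
  up <- 2^contrast$log2fc > fold
  dn <- 2^(-contrast$log2fc) > fold
  if (!all(is.na(contrast$p))) {
    ok <- !is.na(contrast$p) & contrast$p < p_max
    up <- up & ok
    dn <- dn & ok
  }
  ifelse(up, "up", ifelse(dn, "down", "flat"))
}

# the 3x3 direction-pattern taxonomy; numbering fixed so that cluster 4 is
# up-in-mutant AND up-on-activation and cluster 6 is down/down
.CLUSTER_TAXONOMY <- data.frame(
  cluster = 1:9,
  mutant_direction = c("up", "up", "flat", "up", "flat", "down", "down",
                       "down", "flat"),
  activation_direction = c("down", "flat", "up", "up", "down", "down", "up",
                           "flat", "flat"),
  stringsAsFactors = FALSE
)

#' Direction-pattern cluster taxonomy
#'
#' The nine clusters are the cells of the 3 x 3 grid of (mutant-vs-WT
#' quiescent direction) x (activation direction, required concordant across
#' both genotypes and both timepoints). Cluster 4 is up/up; cluster 6 is
#' down/down. Genes flat in every individual contrast are unassigned.
#'
#' @return data.frame with columns `cluster`, `mutant_direction`,
#'   `activation_direction`.
#' @export
clusterTaxonomy <- function() .CLUSTER_TAXONOMY

#' Assign genes to direction-pattern clusters
#'
#' The mutant axis is the direction of the Mut-Q vs WT-Q contrast; the
#' activation axis is "up" ("down") only when all four activation contrasts
#' (WT and mutant, T0 and T12) agree, otherwise "flat". Directions use the
#' strict fold and p thresholds (`> fold`, `p < p_max`); failing either makes
#' a contrast flat. The taxonomy table is emitted to the run log on each
#' call.
#'
#' @param contrasts named list from [standardContrasts()] (elements `mut_q`,
#'   `wt_act_t0`, `wt_act_t12`, `mut_act_t0`, `mut_act_t12`).
#' @param fold,p_max thresholds defining "up"/"down".
#' @return data.frame with columns `gene_id`, `cluster` (integer 1-9 or NA
#'   for genes flat in every contrast), `mutant_direction`,
#'   `activation_direction`.
#' @export
assignPatternCluster <- function(contrasts, fold = 1.5, p_max = 0.1) {
  need <- c("mut_q", "wt_act_t0", "wt_act_t12", "mut_act_t0", "mut_act_t12")
  missing <- setdiff(need, names(contrasts))
  if (length(missing)) {
    stop("missing contrasts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids <- contrasts$mut_q$gene_id
  for (nm in need[-1]) {
    if (!identical(contrasts[[nm]]$gene_id, ids)) {
      stop("contrasts must cover the same genes in the same order",
           call. = FALSE)
    }
  }
  dirs <- lapply(contrasts[need], .direction, fold = fold, p_max = p_max)
  act <- do.call(cbind, dirs[-1])
  act_dir <- ifelse(apply(act == "up", 1L, all), "up",
                    ifelse(apply(act == "down", 1L, all), "down", "flat"))
  mut_dir <- dirs$mut_q
  key <- paste(mut_dir, act_dir)
  tax_key <- paste(.CLUSTER_TAXONOMY$mutant_direction,
                   .CLUSTER_TAXONOMY$activation_direction)
  cluster <- .CLUSTER_TAXONOMY$cluster[match(key, tax_key)]
  all_flat <- mut_dir == "flat" & apply(act == "flat", 1L, all)
  cluster[all_flat] <- NA_integer_
  message("direction-pattern taxonomy (cluster: mutant/activation): ",
          paste(sprintf("%d:%s/%s", .CLUSTER_TAXONOMY$cluster,
                        .CLUSTER_TAXONOMY$mutant_direction,
                        .CLUSTER_TAXONOMY$activation_direction),
                collapse = " "))
  data.frame(gene_id = ids, cluster = cluster,
             mutant_direction = mut_dir, activation_direction = act_dir,
             stringsAsFactors = FALSE)
}

#' Select primed genes from the mutant quiescent contrast
#'
#' Genes over `fold`-fold up- or down-regulated in mutant vs WT quiescent
#' HSCs at `p < p_max`. Both thresholds are strict, so a gene at exactly
#' 1.5-fold is excluded.
#'
#' @param contrast Mut-Q vs WT-Q contrast data.frame from
#'   [expressionContrast()].
#' @param fold linear fold-change threshold (strict >).
#' @param p_max p-value threshold (strict <).
#' @return list with character vectors `up` and `down`.
#' @export
selectPrimedGenes <- function(contrast, fold = 1.5, p_max = 0.1) {
  stopifnot(all(c("gene_id", "log2fc", "p") %in% names(contrast)))
  p_ok <- !is.na(contrast$p) & contrast$p < p_max
  list(
    up = contrast$gene_id[2^contrast$log2fc > fold & p_ok],
    down = contrast$gene_id[2^(-contrast$log2fc) > fold & p_ok]
  )
}
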