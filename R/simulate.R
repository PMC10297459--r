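#' Construct a simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' planted peaks exceed the >2-fold accessibility filter (fold 2.5), planted
#' genes exceed the >1.5-fold mutant-expression filter (fold 1.8) with
#' moderate log2 replicate noise (SD 0.2, 3 replicates), the bioluminescence
#' trace oscillates at 23.5 h with slow damping over a 7-day recording at
#' 10-minute sampling, and the cohort reproduces the published stratum sizes
#' (146 / 19 / 31 patients below 8, between 8 and 15, and above 15 kPa).
#'
#' @param seed master integer seed; every generator derives a fixed substream
#'   from it, so generators are individually deterministic and
#'   order-independent.
#' @param n_genes,n_chroms,chrom_length,n_peaks,peak_width genome/peak layout.
#' @param n_planted_repressed,n_planted_activated,n_decoys_per_class planted
#'   regulome structure.
#' @param accessibility_fold,expression_fold,expression_noise_sd,n_replicates
#'   effect sizes and noise.
#' @param trace_period_h,trace_amplitude,trace_damping_rate,trace_noise_sd,
#'   trace_duration_h,trace_interval_h,trace_phase_rad,trace_baseline,trace_drift
#'   luminescence trace parameters.
#' @param cohort_sizes,cohort_group_shifts,cohort_biomarker_baseline,
#'   cohort_biomarker_sd cohort structure.
#' @param n_gene_sets,gene_set_size GMT collection layout.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             n_genes = 200L, n_chroms = 4L,
                             chrom_length = 1e6, n_peaks = 200L,
                             n_planted_repressed = 20L,
                             n_planted_activated = 20L,
                             n_decoys_per_class = 10L,
                             peak_width = 500L,
                             accessibility_fold = 2.5,
                             expression_fold = 1.8,
                             expression_noise_sd = 0.2,
                             n_replicates = 3L,
                             trace_period_h = 23.5,
                             trace_amplitude = 1,
                             trace_damping_rate = 0.01,
                             trace_noise_sd = 0.1,
                             trace_duration_h = 168,
                             trace_interval_h = 1 / 6,
                             trace_phase_rad = 0,
                             trace_baseline = 0,
                             trace_drift = 0,
                             cohort_sizes = c(146L, 19L, 31L),
                             cohort_group_shifts = c(0, 5, 20),
                             cohort_biomarker_baseline = 50,
                             cohort_biomarker_sd = 8,
                             n_gene_sets = 20L,
                             gene_set_size = 20L) {
  new("SimulationConfig",
      seed = as.integer(seed),
      n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
      chrom_length = as.numeric(chrom_length),
      n_peaks = as.integer(n_peaks),
      n_planted_repressed = as.integer(n_planted_repressed),
      n_planted_activated = as.integer(n_planted_activated),
      n_decoys_per_class = as.integer(n_decoys_per_class),
      peak_width = as.integer(peak_width),
      accessibility_fold = accessibility_fold,
      expression_fold = expression_fold,
      expression_noise_sd = expression_noise_sd,
      n_replicates = as.integer(n_replicates),
      trace_period_h = trace_period_h, trace_amplitude = trace_amplitude,
      trace_damping_rate = trace_damping_rate,
      trace_noise_sd = trace_noise_sd,
      trace_duration_h = trace_duration_h,
      trace_interval_h = trace_interval_h,
      trace_phase_rad = trace_phase_rad,
      trace_baseline = trace_baseline, trace_drift = trace_drift,
      cohort_sizes = as.integer(cohort_sizes),
      cohort_group_shifts = as.numeric(cohort_group_shifts),
      cohort_biomarker_baseline = cohort_biomarker_baseline,
      cohort_biomarker_sd = cohort_biomarker_sd,
      n_gene_sets = as.integer(n_gene_sets),
      gene_set_size = as.integer(gene_set_size))
}

# deterministic substream per generator; offsets fixed so generators are
# order-independent
.substream <- function(config, offset) set.seed(config@seed * 1000L + offset)

.MIN_GENE_GAP <- 3000L

#' Transcription start sites of a gene table
#'
#' Coordinates are 0-based half-open throughout (BED convention): the TSS of
#' a + strand gene is `start`, of a - strand gene `end - 1`.
#'
#' @param genes gene annotation data.frame (`gene_id`, `symbol`, `chrom`,
#'   `strand`, `start`, `end`).
#' @return integer vector of TSS positions, one per row.
#' @export
tssOf <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes (lengths 1-4 kb, inter-gene gaps of at least
#' 3 kb) on `n_chroms` chromosomes, assigning random strands. Errors if the
#' requested gene count cannot be packed into the chromosome length.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @examples
#' genes <- generateGenome(simulationConfig(seed = 1, n_genes = 20))
#' head(genes)
#' @export
generateGenome <- function(config) {
  validObject(config)
  .substream(config, 11L)
  per_chrom <- diff(floor(seq(0, config@n_genes,
                              length.out = config@n_chroms + 1L)))
  out <- vector("list", config@n_chroms)
  idx <- 0L
  for (ci in seq_len(config@n_chroms)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    lens <- sample(1000:4000, n, replace = TRUE)
    needed <- sum(lens) + (n + 1L) * .MIN_GENE_GAP
    if (needed > config@chrom_length) {
      stop("capacity: cannot place ", n, " genes (need ", needed,
           " bp) on a chromosome of ", config@chrom_length, " bp",
           call. = FALSE)
    }
    slack <- config@chrom_length - needed
    w <- stats::runif(n + 1L)
    extra <- floor(slack * w / sum(w))
    gaps <- .MIN_GENE_GAP + extra
    starts <- cumsum(c(gaps[1L], lens[-n] + gaps[2:n]))
    ids <- idx + seq_len(n)
    out[[ci]] <- data.frame(
      gene_id = sprintf("G%04d", ids),
      symbol = sprintf("GENE%04d", ids),
      chrom = paste0("chr", ci),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = as.integer(starts),
      end = as.integer(starts + lens),
      stringsAsFactors = FALSE
    )
    idx <- idx + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Choose which genes carry planted regulome and decoy roles
#'
#' Samples disjoint gene sets: CLOCK-repressed and CLOCK-activated regulome
#' genes, plus three decoy classes, each engineered downstream to fail
#' exactly one regulome filter. Peak ids are filled in by [generatePeaks()].
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene table from [generateGenome()].
#' @return a [GroundTruth-class] object (with `motif_peaks` still empty).
#' @export
plantGroundTruth <- function(config, genes) {
  validObject(config)
  .substream(config, 23L)
  need <- config@n_planted_repressed + config@n_planted_activated +
    3L * config@n_decoys_per_class
  picks <- sample(genes$gene_id, need)
  cut1 <- config@n_planted_repressed
  cut2 <- cut1 + config@n_planted_activated
  d <- config@n_decoys_per_class
  new("GroundTruth",
      repressed = sort(picks[seq_len(cut1)]),
      activated = sort(picks[cut1 + seq_len(config@n_planted_activated)]),
      motif_peaks = character(0),
      decoy_no_motif = sort(picks[cut2 + seq_len(d)]),
      decoy_no_fold = sort(picks[cut2 + d + seq_len(d)]),
      decoy_no_expr = sort(picks[cut2 + 2L * d + seq_len(d)]),
      enriched_term = "SET_PLANTED",
      true_period_h = config@trace_period_h)
}

.random_seq <- function(width) {
  paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
}

.seq_without_ebox <- function(width) {
  repeat {
    s <- .random_seq(width)
    if (!grepl("CACGTG", s, fixed = TRUE)) return(s)
  }
}

.embed_ebox <- function(s) {
  w <- nchar(s)
  # offset >= 5 bp from either peak edge
  pos <- sample(6:(w - 10L), 1L)
  paste0(substr(s, 1L, pos - 1L), "CACGTG", substr(s, pos + 6L, w))
}

#' Generate ATAC-style peaks with planted motif and accessibility structure
#'
#' Every planted regulome gene (and every decoy gene) receives one peak placed
#' 100-400 bp upstream of its TSS, close enough that the gene is that peak's
#' nearest gene. Planted peaks carry an embedded canonical E-box (CACGTG, its
#' own reverse complement) at least 5 bp from the peak edges and a qHSC/aHSC
#' concentration ratio of exactly `accessibility_fold`. Decoy peaks lack
#' exactly one property: `decoy_no_motif` peaks are scrubbed of E-boxes,
#' `decoy_no_fold` peaks have equal concentrations, and `decoy_no_expr` peaks
#' are complete but their gene gets no expression effect. Remaining background
#' peaks are placed uniformly with i.i.d. uniform ACGT sequence and
#' concentration ratios bounded well inside the 2-fold filter.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene table from [generateGenome()].
#' @param truth [GroundTruth-class] from [plantGroundTruth()].
#' @return list with `peaks` (data.frame: `id`, `chrom`, `start`, `end`,
#'   `conc_q`, `conc_a`), `sequences` (named [Biostrings::DNAStringSet]) and
#'   `truth` (updated with `motif_peaks`).
#' @export
generatePeaks <- function(config, genes, truth) {
  validObject(config)
  .substream(config, 37L)
  W <- config@peak_width
  targets <- c(truth@repressed, truth@activated, truth@decoy_no_motif,
               truth@decoy_no_fold, truth@decoy_no_expr)
  n_target <- length(targets)
  n_bg <- config@n_peaks - n_target
  tss <- tssOf(genes)
  names(tss) <- genes$gene_id
  strand <- stats::setNames(genes$strand, genes$gene_id)
  chrom <- stats::setNames(genes$chrom, genes$gene_id)

  start <- integer(config@n_peaks)
  chr <- character(config@n_peaks)
  seqs <- character(config@n_peaks)
  conc_a <- exp(stats::rnorm(config@n_peaks, log(20), 0.3))
  conc_q <- numeric(config@n_peaks)

  has_motif <- rep(FALSE, config@n_peaks)
  no_motif_set <- truth@decoy_no_motif
  no_fold_set <- truth@decoy_no_fold

  for (i in seq_len(n_target)) {
    g <- targets[i]
    off <- sample(100:400, 1L)
    # upstream of the TSS on the gene's own strand; genome layout guarantees
    # >= 3 kb clearance so the peak stays inside the chromosome and the
    # target gene remains its nearest gene
    if (strand[g] == "+") {
      start[i] <- tss[g] - off - W
    } else {
      start[i] <- tss[g] + off
    }
    chr[i] <- chrom[g]
    if (g %in% no_motif_set) {
      seqs[i] <- .seq_without_ebox(W)
    } else {
      seqs[i] <- .embed_ebox(.random_seq(W))
      has_motif[i] <- TRUE
    }
    conc_q[i] <- if (g %in% no_fold_set) conc_a[i] else
      conc_a[i] * config@accessibility_fold
  }
  if (n_bg > 0L) {
    j <- n_target + seq_len(n_bg)
    chr[j] <- paste0("chr", sample(config@n_chroms, n_bg, replace = TRUE))
    start[j] <- floor(stats::runif(n_bg, 0, config@chrom_length - W))
    seqs[j] <- vapply(j, function(k) .random_seq(W), character(1))
    # ratio bounded in (2^-0.8, 2^0.8): never passes the >2-fold filter
    conc_q[j] <- conc_a[j] * 2^stats::runif(n_bg, -0.8, 0.8)
  }

  ids <- sprintf("peak%04d", seq_len(config@n_peaks))
  peaks <- data.frame(id = ids, chrom = chr, start = as.integer(start),
                      end = as.integer(start + W),
                      conc_q = conc_q, conc_a = conc_a,
                      stringsAsFactors = FALSE)
  sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  truth@motif_peaks <- ids[has_motif]
  list(peaks = peaks, sequences = sequences, truth = truth)
}

.CONDITIONS <- c("WT-Q", "Mut-Q", "WT-A-T0", "Mut-A-T0", "WT-A-T12",
                 "Mut-A-T12")

#' Generate a six-condition log2 expression matrix
#'
#' Per-gene log2 values are baseline + planted effect + Normal(0, noise SD).
#' Planted repressed genes gain +log2(expression_fold) in Mut-Q (so they are
#' up in the mutant quiescent state) and +2 log2(fold) in all four activated
#' conditions, making them concordantly activation-correlated in both
#' genotypes; activated genes are mirrored downward. Decoy genes of the
#' no-motif and no-fold classes get the Mut-Q effect only (their expression
#' filter must pass); no-expression decoys get none.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene table.
#' @param truth [GroundTruth-class].
#' @param n_replicates replicates per condition (default from config).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `log2`
#'   and colData columns `condition`, `replicate`.
#' @export
generateExpression <- function(config, genes, truth,
                               n_replicates = config@n_replicates) {
  validObject(config)
  .substream(config, 53L)
  ng <- nrow(genes)
  baseline <- stats::runif(ng, 6, 12)
  e <- log2(config@expression_fold)
  eff <- matrix(0, nrow = ng, ncol = length(.CONDITIONS),
                dimnames = list(genes$gene_id, .CONDITIONS))
  act_cols <- c("WT-A-T0", "Mut-A-T0", "WT-A-T12", "Mut-A-T12")
  eff[truth@repressed, "Mut-Q"] <- e
  eff[truth@repressed, act_cols] <- 2 * e
  eff[truth@activated, "Mut-Q"] <- -e
  eff[truth@activated, act_cols] <- -2 * e
  eff[c(truth@decoy_no_motif, truth@decoy_no_fold), "Mut-Q"] <- e

  cond <- rep(.CONDITIONS, each = n_replicates)
  repl <- rep(seq_len(n_replicates), times = length(.CONDITIONS))
  vals <- matrix(0, nrow = ng, ncol = length(cond),
                 dimnames = list(genes$gene_id, paste0(cond, "_", repl)))
  for (j in seq_along(cond)) {
    vals[, j] <- baseline + eff[, cond[j]] +
      stats::rnorm(ng, 0, config@expression_noise_sd)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = vals),
    colData = S4Vectors::DataFrame(condition = cond, replicate = repl,
                                   row.names = colnames(vals))
  )
}

#' Evaluate a damped cosine with linear baseline
#'
#' `amplitude * exp(-damping * t) * cos(2 pi t / period + phase) +
#'  baseline + drift * t`, the deterministic part of the luminescence model.
#'
#' @param t times in hours.
#' @param amplitude,damping,period,phase,baseline,drift model parameters;
#'   `period` must be positive and `damping` non-negative.
#' @return numeric vector of signal values.
#' @export
dampedCosine <- function(t, amplitude = 1, damping = 0, period = 24,
                         phase = 0, baseline = 0, drift = 0) {
  if (period <= 0) stop("period must be positive", call. = FALSE)
  if (damping < 0) stop("damping must be non-negative", call. = FALSE)
  amplitude * exp(-damping * t) * cos(2 * pi * t / period + phase) +
    baseline + drift * t
}

#' Generate a synthetic bioluminescence trace
#'
#' Uniformly sampled damped cosine with linear baseline and additive Gaussian
#' noise, emulating a PER2::LUC recording whose amplitude decays through
#' gradual desynchronisation in culture. The recording must span at least
#' three full periods.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional seed overriding the config substream (used to draw
#'   independent noise realisations at fixed trace parameters).
#' @return data.frame with columns `time_h`, `value`.
#' @examples
#' tr <- generateTrace(simulationConfig(seed = 1))
#' nrow(tr)  # 1009 samples: 168 h at 10-min sampling, endpoints inclusive
#' @export
generateTrace <- function(config, seed = NULL) {
  validObject(config)
  if (config@trace_duration_h < 3 * config@trace_period_h) {
    stop("trace duration must cover at least 3 periods", call. = FALSE)
  }
  if (is.null(seed)) .substream(config, 71L) else set.seed(seed)
  n_step <- round(config@trace_duration_h / config@trace_interval_h)
  t <- (0:n_step) * config@trace_interval_h
  v <- dampedCosine(t, config@trace_amplitude, config@trace_damping_rate,
                    config@trace_period_h, config@trace_phase_rad,
                    config@trace_baseline, config@trace_drift) +
    stats::rnorm(length(t), 0, config@trace_noise_sd)
  data.frame(time_h = t, value = v)
}

#' Generate a synthetic liver-fibrosis cohort
#'
#' Three severity groups defined by their liver stiffness stratum (LSM drawn
#' within <8, 8-15 and >15 kPa respectively); the serum biomarker is baseline
#' + group shift + Gaussian noise with shifts monotone non-decreasing in
#' severity. Age, AST, ALT and platelets are drawn from plausible clinical
#' ranges so the FIB-4 score is computable for every patient.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional seed overriding the config substream.
#' @return data.frame with columns `patient_id`, `age`, `ast`, `alt`,
#'   `platelets`, `lsm_kpa`, `biomarker`, `diagnosis`.
#' @export
generateCohort <- function(config, seed = NULL) {
  validObject(config)
  if (is.null(seed)) .substream(config, 89L) else set.seed(seed)
  sizes <- config@cohort_sizes
  n <- sum(sizes)
  grp <- rep(1:3, times = sizes)
  lsm <- numeric(n)
  lsm[grp == 1] <- stats::runif(sizes[1], 2, 7.9)
  lsm[grp == 2] <- stats::runif(sizes[2], 8, 15)
  lsm[grp == 3] <- stats::runif(sizes[3], 15.1, 40)
  biomarker <- config@cohort_biomarker_baseline +
    config@cohort_group_shifts[grp] +
    stats::rnorm(n, 0, config@cohort_biomarker_sd)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(stats::runif(n, 30, 78)),
    ast = round(stats::runif(n, 15, 90), 1),
    alt = round(stats::runif(n, 15, 90), 1),
    platelets = round(stats::runif(n, 120, 350)),
    lsm_kpa = round(lsm, 1),
    biomarker = biomarker,
    diagnosis = sample(c("NAFLD", "ArLD", "other"), n, replace = TRUE,
                       prob = c(0.68, 0.12, 0.20)),
    stringsAsFactors = FALSE
  )
}

#' Generate a GMT gene-set collection with one planted term
#'
#' The planted term draws at least 80% of its members from the planted
#' repressed genes; the remaining terms are random draws from the genome, so
#' their overlap with any query follows the hypergeometric null.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene table.
#' @param truth [GroundTruth-class]; `truth@enriched_term` names the planted
#'   term.
#' @return named list of character vectors (gene ids) with a `descriptions`
#'   attribute, the in-memory form read and written by [readGMT()] /
#'   [writeGMT()].
#' @export
generateGeneSets <- function(config, genes, truth) {
  validObject(config)
  .substream(config, 101L)
  K <- config@gene_set_size
  n_rep <- length(truth@repressed)
  k_planted <- min(n_rep, ceiling(0.85 * K))
  planted <- c(sample(truth@repressed, k_planted),
               sample(setdiff(genes$gene_id, truth@repressed),
                      K - k_planted))
  sets <- vector("list", config@n_gene_sets)
  names(sets) <- c(truth@enriched_term,
                   sprintf("SET%03d", seq_len(config@n_gene_sets - 1L)))
  sets[[1L]] <- sort(planted)
  for (i in 2:config@n_gene_sets) {
    sets[[i]] <- sort(sample(genes$gene_id, sample(10:40, 1L)))
  }
  attr(sets, "descriptions") <- stats::setNames(
    c("planted CLOCK-repressed module",
      sprintf("random gene set %d", seq_len(config@n_gene_sets - 1L))),
    names(sets))
  sets
}

#' Run every generator and assemble a complete synthetic study
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `config`, `genes`, `truth`, `peaks`,
#'   `sequences`, `expression`, `trace`, `cohort`, `gene_sets`.
#' @examples
#' study <- simulateRegulomeStudy(simulationConfig(seed = 1, n_genes = 60,
#'                                                 n_peaks = 80))
#' names(study)
#' @export
simulateRegulomeStudy <- function(config) {
  genes <- generateGenome(config)
  truth <- plantGroundTruth(config, genes)
  pk <- generatePeaks(config, genes, truth)
  truth <- pk$truth
  list(config = config,
       genes = genes,
       truth = truth,
       peaks = pk$peaks,
       sequences = pk$sequences,
       expression = generateExpression(config, genes, truth),
       trace = generateTrace(config),
       cohort = generateCohort(config),
       gene_sets = generateGeneSets(config, genes, truth))
}
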