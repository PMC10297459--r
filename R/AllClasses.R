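#' @import methods
NULL

#' Simulation configuration for a synthetic regulome study
#'
#' Holds every tunable of the synthetic-data generators: genome layout, peak
#' and planted-regulome structure, expression effect sizes and noise,
#' bioluminescence trace parameters and cohort group structure. Validity
#' enforces the constraints that guarantee planted signal clears the
#' downstream filters in the noise-free limit (accessibility fold > 2,
#' expression fold > 1.5).
#'
#' @slot seed integer; master seed, each generator derives its own substream.
#' @slot n_genes,n_chroms,chrom_length,n_peaks genome layout (bp, counts).
#' @slot n_planted_repressed,n_planted_activated counts of regulome genes
#'   planted as CLOCK-repressed (up in mutant) / CLOCK-activated (down).
#' @slot n_decoys_per_class decoy genes per failure class (no motif /
#'   no accessibility fold / no expression change).
#' @slot peak_width bp width of generated peaks.
#' @slot accessibility_fold qHSC/aHSC concentration ratio of planted peaks.
#' @slot expression_fold linear mutant-vs-WT fold change of planted genes.
#' @slot expression_noise_sd per-replicate log2 noise SD.
#' @slot n_replicates replicates per condition.
#' @slot trace_period_h,trace_amplitude,trace_damping_rate,trace_noise_sd,
#'   trace_duration_h,trace_interval_h,trace_phase_rad,trace_baseline,trace_drift
#'   damped-cosine luminescence trace parameters (hours, signal units, per-hour).
#' @slot cohort_sizes integer triple: patients per LSM stratum
#'   (<8, 8-15, >15 kPa).
#' @slot cohort_group_shifts biomarker shift per stratum, monotone
#'   non-decreasing with severity.
#' @slot cohort_biomarker_baseline,cohort_biomarker_sd biomarker location/noise.
#' @slot n_gene_sets,gene_set_size GMT collection layout.
#'
#' @seealso [simulationConfig()] for the user constructor with defaults.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    n_genes = "integer", n_chroms = "integer", chrom_length = "numeric",
    n_peaks = "integer",
    n_planted_repressed = "integer", n_planted_activated = "integer",
    n_decoys_per_class = "integer", peak_width = "integer",
    accessibility_fold = "numeric",
    expression_fold = "numeric", expression_noise_sd = "numeric",
    n_replicates = "integer",
    trace_period_h = "numeric", trace_amplitude = "numeric",
    trace_damping_rate = "numeric", trace_noise_sd = "numeric",
    trace_duration_h = "numeric", trace_interval_h = "numeric",
    trace_phase_rad = "numeric", trace_baseline = "numeric",
    trace_drift = "numeric",
    cohort_sizes = "integer", cohort_group_shifts = "numeric",
    cohort_biomarker_baseline = "numeric", cohort_biomarker_sd = "numeric",
    n_gene_sets = "integer", gene_set_size = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  counts <- c(
    n_genes = object@n_genes, n_chroms = object@n_chroms,
    n_peaks = object@n_peaks, n_replicates = object@n_replicates,
    peak_width = object@peak_width, n_gene_sets = object@n_gene_sets,
    gene_set_size = object@gene_set_size
  )
  if (any(counts <= 0)) {
    msgs <- c(msgs, paste("counts must be > 0:",
                          paste(names(counts)[counts <= 0], collapse = ", ")))
  }
  if (object@chrom_length <= 0) msgs <- c(msgs, "chrom_length must be > 0")
  n_planted <- object@n_planted_repressed + object@n_planted_activated
  if (object@n_planted_repressed < 0L || object@n_planted_activated < 0L ||
      object@n_decoys_per_class < 0L) {
    msgs <- c(msgs, "planted/decoy counts must be >= 0")
  }
  if (n_planted > object@n_genes) {
    msgs <- c(msgs, "n_planted_repressed + n_planted_activated exceeds n_genes")
  }
  if (n_planted + 3L * object@n_decoys_per_class > object@n_genes) {
    msgs <- c(msgs, "planted + decoy genes exceed n_genes")
  }
  if (n_planted + 3L * object@n_decoys_per_class > object@n_peaks) {
    msgs <- c(msgs, "planted + decoy peaks exceed n_peaks")
  }
  if (object@accessibility_fold <= 2) {
    msgs <- c(msgs, "accessibility_fold must be > 2 to clear the peak filter")
  }
  if (object@expression_fold <= 1.5) {
    msgs <- c(msgs, "expression_fold must be > 1.5 to clear the primed-gene filter")
  }
  if (object@expression_noise_sd < 0) msgs <- c(msgs, "expression_noise_sd must be >= 0")
  if (object@trace_period_h <= 0) msgs <- c(msgs, "trace_period_h must be > 0")
  if (object@trace_damping_rate <= 0) msgs <- c(msgs, "trace_damping_rate must be > 0")
  if (object@trace_noise_sd < 0) msgs <- c(msgs, "trace_noise_sd must be >= 0")
  if (object@trace_interval_h <= 0 || object@trace_duration_h <= 0) {
    msgs <- c(msgs, "trace duration and sampling interval must be > 0")
  }
  if (length(object@cohort_sizes) != 3L) {
    msgs <- c(msgs, "cohort_sizes must be a triple")
  } else if (any(object@cohort_sizes <= 0L)) {
    msgs <- c(msgs, "cohort group sizes must all be > 0")
  }
  if (length(object@cohort_group_shifts) != 3L) {
    msgs <- c(msgs, "cohort_group_shifts must be a triple")
  } else if (is.unsorted(object@cohort_group_shifts)) {
    msgs <- c(msgs, "cohort_group_shifts must be monotone non-decreasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' Planted ground truth of a synthetic study
#'
#' Records which genes were planted as CLOCK-repressed or CLOCK-activated,
#' which peaks carry an embedded E-box, the identities of the engineered decoy
#' genes (each built to fail exactly one regulome filter), the planted
#' enriched gene-set term and the true circadian period of the generated
#' trace.
#'
#' @slot repressed,activated character; planted regulome gene ids (disjoint).
#' @slot motif_peaks character; peak ids with an embedded CACGTG.
#' @slot decoy_no_motif,decoy_no_fold,decoy_no_expr character; decoy gene ids
#'   failing, respectively, the motif, accessibility-fold and expression
#'   filter (and only that one).
#' @slot enriched_term character; id of the planted gene-set term.
#' @slot true_period_h numeric; period used by the trace generator.
#' @export
setClass("GroundTruth",
  representation(
    repressed = "character", activated = "character",
    motif_peaks = "character",
    decoy_no_motif = "character", decoy_no_fold = "character",
    decoy_no_expr = "character",
    enriched_term = "character", true_period_h = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (length(intersect(object@repressed, object@activated)) > 0L)
    return("repressed and activated gene sets must be disjoint")
  TRUE
})

#' Position weight matrix with background model
#'
#' Column-stochastic 4 x width probability matrix (rows A, C, G, T) plus the
#' background base frequencies used for log-odds scoring. Scores are reported
#' in bits: sum over positions of log2(p_base / background_base).
#'
#' @slot probs numeric matrix, rows A/C/G/T, columns positions; columns sum to 1.
#' @slot background named numeric(4) summing to 1.
#' @slot pseudocount probability mass used when the matrix was built from counts
#'   (metadata; already folded into `probs`).
#' @slot name character; motif label.
#' @seealso [eboxPWM()], [scanPWM()], [maxScore()]
#' @export
setClass("PWMatrix",
  representation(probs = "matrix", background = "numeric",
                 pseudocount = "numeric", name = "character")
)

setValidity("PWMatrix", function(object) {
  msgs <- character(0)
  if (!identical(rownames(object@probs), c("A", "C", "G", "T")))
    msgs <- c(msgs, "probs must have rows A, C, G, T")
  if (ncol(object@probs) < 4L) msgs <- c(msgs, "motif width must be >= 4")
  if (ncol(object@probs) >= 1L &&
      any(abs(colSums(object@probs) - 1) > 1e-9))
    msgs <- c(msgs, "each position's probabilities must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9)
    msgs <- c(msgs, "background must be 4 frequencies summing to 1")
  if (any(object@probs < 0) || any(object@background <= 0))
    msgs <- c(msgs, "probabilities must be non-negative, background positive")
  if (length(msgs)) msgs else TRUE
})

#' Fitted circadian rhythm parameters
#'
#' Result of [fitDampedCosine()]: the least-squares parameters of
#' A * exp(-lambda t) * cos(2 pi t / T + phi) on a detrended trace, the
#' goodness of fit and the rhythmicity call.
#'
#' @slot period_h fitted period T (hours).
#' @slot amplitude fitted A (signal units, at t = 0).
#' @slot damping_rate fitted lambda (per hour, >= 0).
#' @slot phase_rad fitted phi (radians).
#' @slot r_squared variance explained by the fit, in [0, 1].
#' @slot rhythmic TRUE iff converged, r_squared >= threshold and the period
#'   lies within the search band.
#' @slot converged optimiser convergence flag.
#' @slot band numeric(2); period search band (hours).
#' @slot init_period_h periodogram period used to initialise the winning start.
#' @slot n_points number of samples used in the fit.
#' @export
setClass("RhythmFit",
  representation(
    period_h = "numeric", amplitude = "numeric", damping_rate = "numeric",
    phase_rad = "numeric", r_squared = "numeric",
    rhythmic = "logical", converged = "logical",
    band = "numeric", init_period_h = "numeric", n_points = "integer"
  )
)

setValidity("RhythmFit", function(object) {
  msgs <- character(0)
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    msgs <- c(msgs, "band must be an increasing pair of hours")
  if (!is.na(object@damping_rate) && object@damping_rate < 0)
    msgs <- c(msgs, "damping_rate must be >= 0")
  if (!is.na(object@r_squared) &&
      (object@r_squared < -1e-9 || object@r_squared > 1 + 1e-9))
    msgs <- c(msgs, "r_squared must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome:  ", object@n_genes, " genes on ", object@n_chroms,
      " chromosomes of ", format(object@chrom_length, big.mark = ","),
      " bp\n", sep = "")
  cat("  peaks:   ", object@n_peaks, " (planted ",
      object@n_planted_repressed, " repressed + ",
      object@n_planted_activated, " activated, ",
      3L * object@n_decoys_per_class, " decoys), accessibility fold ",
      object@accessibility_fold, "\n", sep = "")
  cat("  expr:    fold ", object@expression_fold, ", log2 noise SD ",
      object@expression_noise_sd, ", ", object@n_replicates,
      " replicates/condition\n", sep = "")
  cat("  trace:   period ", object@trace_period_h, " h, damping ",
      object@trace_damping_rate, "/h, ", object@trace_duration_h,
      " h at ", round(object@trace_interval_h * 60), " min\n", sep = "")
  cat("  cohort:  sizes ", paste(object@cohort_sizes, collapse = "/"),
      ", biomarker shifts ",
      paste(object@cohort_group_shifts, collapse = "/"), "\n", sep = "")
  invisible(object)
})

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", length(object@repressed), " repressed, ",
      length(object@activated), " activated planted genes; ",
      length(object@motif_peaks), " motif peaks; ",
      length(object@decoy_no_motif) + length(object@decoy_no_fold) +
        length(object@decoy_no_expr), " decoy genes; planted term '",
      object@enriched_term, "'; true period ", object@true_period_h,
      " h\n", sep = "")
  invisible(object)
})

#' @export
setMethod("show", "PWMatrix", function(object) {
  cat("PWMatrix '", object@name, "': width ", ncol(object@probs),
      ", max score ", round(maxScore(object), 3), " bits, consensus ",
      consensusOf(object), "\n", sep = "")
  invisible(object)
})

#' @export
setMethod("show", "RhythmFit", function(object) {
  cat("RhythmFit: period ", round(object@period_h, 3), " h, amplitude ",
      signif(object@amplitude, 4), ", damping ",
      signif(object@damping_rate, 4), "/h, phase ",
      round(object@phase_rad, 3), " rad\n", sep = "")
  cat("  R^2 = ", round(object@r_squared, 4), "; ",
      if (isTRUE(object@rhythmic)) "rhythmic" else "not rhythmic",
      " (band ", object@band[1], "-", object@band[2], " h, ",
      object@n_points, " points, init ", round(object@init_period_h, 2),
      " h)\n", sep = "")
  invisible(object)
})

#' Accessors for fitted rhythm parameters
#'
#' @param fit a [RhythmFit-class] object.
#' @return `periodHours`, `dampingRate` and `fitRsquared` return numerics;
#'   `isRhythmic` a logical.
#' @export
periodHours <- function(fit) { stopifnot(is(fit, "RhythmFit")); fit@period_h }

#' @rdname periodHours
#' @export
dampingRate <- function(fit) { stopifnot(is(fit, "RhythmFit")); fit@damping_rate }

#' @rdname periodHours
#' @export
fitRsquared <- function(fit) { stopifnot(is(fit, "RhythmFit")); fit@r_squared }

#' @rdname periodHours
#' @export
isRhythmic <- function(fit) { stopifnot(is(fit, "RhythmFit")); fit@rhythmic }

#' Accessors for planted ground truth
#'
#' @param truth a [GroundTruth-class] object.
#' @return character vectors of gene ids (`repressedGenes`, `activatedGenes`,
#'   `decoyGenes`) or peak ids (`motifPeaks`).
#' @export
repressedGenes <- function(truth) { stopifnot(is(truth, "GroundTruth")); truth@repressed }

#' @rdname repressedGenes
#' @export
activatedGenes <- function(truth) { stopifnot(is(truth, "GroundTruth")); truth@activated }

#' @rdname repressedGenes
#' @export
motifPeaks <- function(truth) { stopifnot(is(truth, "GroundTruth")); truth@motif_peaks }

#' @rdname repressedGenes
#' @export
decoyGenes <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  c(truth@decoy_no_motif, truth@decoy_no_fold, truth@decoy_no_expr)
}
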