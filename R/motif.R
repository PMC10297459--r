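#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (n_sites + pseudocount)`.
#'
#' @param sites character vector of equal-length A/C/G/T strings.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount total pseudocount mass spread according to background.
#' @param name motif label.
#' @return a [PWMatrix-class].
#' @export
pwmFromSites <- function(sites, background = rep(0.25, 4),
                         pseudocount = 0.01, name = "motif") {
  stopifnot(length(sites) >= 1L, length(unique(nchar(sites))) == 1L)
  w <- nchar(sites[1L])
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = 4L, ncol = w, dimnames = list(bases, NULL))
  chars <- do.call(rbind, strsplit(toupper(sites), ""))
  for (j in seq_len(w)) {
    counts <- table(factor(chars[, j], levels = bases))
    mat[, j] <- (as.numeric(counts) + pseudocount * background) /
      (length(sites) + pseudocount)
  }
  names(background) <- bases
  new("PWMatrix", probs = mat, background = background,
      pseudocount = pseudocount, name = name)
}

#' The canonical CLOCK:BMAL1 E-box matrix
#'
#' A 6-position PWM concentrated on CACGTG (the palindromic E-box bound by
#' the CLOCK:BMAL1 dimer), built from the single consensus site with the
#' given pseudocount over a uniform background. Users may substitute any
#' matrix, e.g. a JASPAR CLOCK PWM read with [readMEME()].
#'
#' @param pseudocount pseudocount mass (default 0.01).
#' @return a [PWMatrix-class] named "Ebox_CACGTG".
#' @examples
#' maxScore(eboxPWM())
#' @export
eboxPWM <- function(pseudocount = 0.01) {
  pwmFromSites("CACGTG", pseudocount = pseudocount, name = "Ebox_CACGTG")
}

#' Maximum attainable log-odds score of a PWM, in bits
#'
#' @param pwm a [PWMatrix-class].
#' @return numeric scalar.
#' @export
maxScore <- function(pwm) {
  lo <- log2(pwm@probs / pwm@background)
  sum(apply(lo, 2L, max))
}

#' Consensus sequence (highest-probability base per position)
#' @param pwm a [PWMatrix-class].
#' @return character scalar.
#' @export
consensusOf <- function(pwm) {
  paste(rownames(pwm@probs)[apply(pwm@probs, 2L, which.max)], collapse = "")
}

# integer-encode a sequence; A=1 C=2 G=3 T=4, anything else (N) = 5
.encode <- function(seq) {
  x <- strsplit(toupper(as.character(seq)), "")[[1L]]
  m <- match(x, c("A", "C", "G", "T"))
  m[is.na(m)] <- 5L
  m
}

# log-odds lookup with a 5th row of -Inf so N-containing windows score -Inf
.lo5 <- function(pwm) {
  rbind(log2(pwm@probs / pwm@background), N = rep(-Inf, ncol(pwm@probs)))
}

# minus-strand scoring = plus-strand scoring with the reverse-complemented
# matrix: complement the base rows, reverse the columns
.lo5_rc <- function(lo5) {
  lo5[c(4L, 3L, 2L, 1L, 5L), rev(seq_len(ncol(lo5))), drop = FALSE]
}

.window_scores <- function(codes, lo5) {
  w <- ncol(lo5)
  L <- length(codes)
  n <- L - w + 1L
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + lo5[cbind(codes[j:(j + n - 1L)], j)]
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window on both strands in log-odds bits; windows overlapping
#' an N score -Inf. Hits are all windows at or above `threshold`, reported in
#' ascending 0-based offset, with minus-strand hits placed at the plus-strand
#' coordinate of their window start. A sequence shorter than the motif yields
#' an empty result.
#'
#' @param seq a character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @param pwm a [PWMatrix-class].
#' @param threshold score threshold in bits; default
#'   `threshold_frac * maxScore(pwm)`.
#' @param threshold_frac fraction of the maximum attainable score used when
#'   `threshold` is NULL (default 0.8, common practice for PWM calling).
#' @return data.frame with columns `offset` (0-based), `strand` (+/-),
#'   `score` (bits).
#' @examples
#' scanPWM("TTTCACGTGTTT", eboxPWM())
#' @export
scanPWM <- function(seq, pwm, threshold = NULL, threshold_frac = 0.8) {
  stopifnot(is(pwm, "PWMatrix"))
  if (is.null(threshold)) threshold <- threshold_frac * maxScore(pwm)
  codes <- .encode(seq)
  w <- ncol(pwm@probs)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(codes) < w) return(empty)
  lo5 <- .lo5(pwm)
  fwd <- .window_scores(codes, lo5)
  rev_ <- .window_scores(codes, .lo5_rc(lo5))
  offs <- seq_along(fwd) - 1L
  fi <- which(fwd >= threshold)
  ri <- which(rev_ >= threshold)
  hits <- rbind(
    data.frame(offset = offs[fi], strand = rep("+", length(fi)),
               score = fwd[fi], stringsAsFactors = FALSE),
    data.frame(offset = offs[ri], strand = rep("-", length(ri)),
               score = rev_[ri], stringsAsFactors = FALSE)
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a set of peak sequences
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector)
#'   of peak sequences.
#' @inheritParams scanPWM
#' @return data.frame of hits with a leading `peak_id` column.
#' @export
scanPeaks <- function(seqs, pwm, threshold = NULL, threshold_frac = 0.8) {
  nms <- names(seqs)
  if (is.null(nms)) stop("peak sequences must be named", call. = FALSE)
  out <- lapply(nms, function(id) {
    h <- scanPWM(seqs[[id]], pwm, threshold, threshold_frac)
    if (nrow(h)) cbind(peak_id = id, h, stringsAsFactors = FALSE) else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peak_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Does a peak sequence contain at least one motif hit?
#'
#' @inheritParams scanPeaks
#' @return named logical vector, one element per sequence.
#' @export
peakHasMotif <- function(seqs, pwm, threshold = NULL, threshold_frac = 0.8) {
  if (is.null(names(seqs))) stop("peak sequences must be named", call. = FALSE)
  vapply(names(seqs), function(id) {
    nrow(scanPWM(seqs[[id]], pwm, threshold, threshold_frac)) > 0L
  }, logical(1))
}

#' One-sided Fisher enrichment test on motif counts
#'
#' Tests over-representation of motif-bearing peaks in the foreground against
#' the background via the 2 x 2 table (has motif / lacks motif) x
#' (foreground / background). The odds ratio is the sample cross-product
#' ratio with a Haldane correction (+0.5 to every cell) when any cell is
#' zero.
#'
#' @param k_fg,n_fg motif-bearing and total foreground peaks.
#' @param k_bg,n_bg motif-bearing and total background peaks.
#' @return list with `odds_ratio`, `p` (one-sided Fisher exact) and `table`.
#' @export
fisherEnrichment <- function(k_fg, n_fg, k_bg, n_bg) {
  stopifnot(k_fg <= n_fg, k_bg <= n_bg, k_fg >= 0, k_bg >= 0)
  tab <- matrix(c(k_fg, n_fg - k_fg, k_bg, n_bg - k_bg), nrow = 2L,
                dimnames = list(motif = c("yes", "no"),
                                set = c("foreground", "background")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
    ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(odds_ratio = unname(or), p = p, table = tab)
}

#' Motif enrichment of a foreground peak set against a background
#'
#' @param foreground,background named sequence sets
#'   ([Biostrings::DNAStringSet] or named character vectors); both must be
#'   non-empty.
#' @inheritParams scanPWM
#' @return list from [fisherEnrichment()].
#' @export
motifEnrichment <- function(foreground, background, pwm, threshold = NULL,
                            threshold_frac = 0.8) {
  if (length(foreground) == 0L || length(background) == 0L) {
    stop("foreground and background peak sets must be non-empty",
         call. = FALSE)
  }
  fg <- peakHasMotif(foreground, pwm, threshold, threshold_frac)
  bg <- peakHasMotif(background, pwm, threshold, threshold_frac)
  fisherEnrichment(sum(fg), length(fg), sum(bg), length(bg))
}

#' Read and write MEME-format motif matrices
#'
#' Minimal MEME text format: a `MOTIF` line followed by a
#' `letter-probability matrix:` header and one row of four probabilities per
#' position. Background frequencies are taken from the
#' `Background letter frequencies` block when present, else uniform.
#'
#' @param path MEME-format file.
#' @param pwm a [PWMatrix-class].
#' @return `readMEME` returns a [PWMatrix-class]; `writeMEME` returns `path`
#'   invisibly.
#' @export
readMEME <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  motif_i <- grep("^MOTIF", lines)
  if (!length(motif_i)) stop("no MOTIF block found in ", path, call. = FALSE)
  name <- strsplit(trimws(lines[motif_i[1L]]), "\\s+")[[1L]][2L]
  hdr_i <- grep("^letter-probability matrix", lines)
  hdr_i <- hdr_i[hdr_i > motif_i[1L]][1L]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr_i]))
  rows <- lines[(hdr_i + 1L):(hdr_i + w)]
  mat <- t(vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
  }, numeric(4)))
  probs <- t(mat)
  dimnames(probs) <- list(c("A", "C", "G", "T"), NULL)
  # renormalise against truncation in the text representation
  probs <- sweep(probs, 2L, colSums(probs), "/")
  names(bg) <- c("A", "C", "G", "T")
  new("PWMatrix", probs = probs, background = bg, pseudocount = NA_real_,
      name = name)
}

#' @rdname readMEME
#' @export
writeMEME <- function(pwm, path) {
  stopifnot(is(pwm, "PWMatrix"))
  w <- ncol(pwm@probs)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f",
            pwm@background[1], pwm@background[2],
            pwm@background[3], pwm@background[4]), "",
    paste("MOTIF", pwm@name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0", w),
    vapply(seq_len(w), function(j) {
      sprintf(" %.6f %.6f %.6f %.6f", pwm@probs[1, j], pwm@probs[2, j],
              pwm@probs[3, j], pwm@probs[4, j])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
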