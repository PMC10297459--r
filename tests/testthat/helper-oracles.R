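# Independent brute-force oracles. These deliberately share no code with the
# implementation: naive loops, explicit combinatorial sums.

# naive O(n * w) double-strand PWM re-scorer
oracle_scan <- function(seq, pwm, threshold) {
  s <- strsplit(toupper(seq), "")[[1]]
  probs <- pwm@probs
  bg <- pwm@background
  w <- ncol(probs)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_window <- function(chars) {
    sc <- 0
    for (j in seq_len(w)) {
      b <- chars[j]
      if (!b %in% c("A", "C", "G", "T")) return(-Inf)
      sc <- sc + log2(probs[b, j] / bg[b])
    }
    sc
  }
  out <- NULL
  if (length(s) >= w) {
    for (off in 0:(length(s) - w)) {
      win <- s[(off + 1):(off + w)]
      sp <- score_window(win)
      sm <- score_window(rev(unname(comp[win])))
      if (sp >= threshold) out <- rbind(out, data.frame(
        offset = off, strand = "+", score = sp, stringsAsFactors = FALSE))
      if (sm >= threshold) out <- rbind(out, data.frame(
        offset = off, strand = "-", score = sm, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# hypergeometric upper tail by explicit summation of the pmf
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# one-sided Fisher p for a 2x2 table via the same tail
oracle_fisher_greater <- function(k_fg, n_fg, k_bg, n_bg) {
  oracle_hyper_tail(k_fg, k_fg + k_bg, n_fg + n_bg, n_fg)
}

# Benjamini-Hochberg by the literal step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# exhaustive nearest gene by TSS distance, lexicographic tie-break
oracle_nearest <- function(peak, genes) {
  best_gene <- NA_character_
  best_d <- Inf
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != peak$chrom) next
    tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1L
    d <- if (tss >= peak$start && tss < peak$end) 0L else
      min(abs(tss - peak$start), abs(tss - (peak$end - 1L)))
    if (d < best_d || (d == best_d && !is.na(best_gene) &&
                       genes$gene_id[i] < best_gene)) {
      best_d <- d
      best_gene <- genes$gene_id[i]
    }
  }
  list(gene = best_gene, dist = if (is.infinite(best_d)) NA else best_d)
}

# a small study configuration used across tests to keep runtimes short
smallConfig <- function(seed = 1L, ...) {
  simulationConfig(seed = seed, n_genes = 60L, n_chroms = 2L,
                   chrom_length = 6e5, n_peaks = 80L,
                   n_planted_repressed = 8L, n_planted_activated = 8L,
                   n_decoys_per_class = 4L, n_gene_sets = 8L,
                   gene_set_size = 8L, ...)
}
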