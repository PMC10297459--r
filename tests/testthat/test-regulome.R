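toy_genes <- function() {
  data.frame(
    gene_id = c("G1", "G2", "G3"),
    symbol = c("A", "B", "C"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(1000L, 5000L, 2000L),
    end = c(2000L, 6000L, 3000L),
    stringsAsFactors = FALSE
  )
}

test_that("differential peak selection is strict and symmetric", {
  pk <- data.frame(id = c("p1", "p2", "p3", "p4"),
                   chrom = "chr1", start = 0L, end = 500L,
                   conc_q = c(10, 5, 10, 2),
                   conc_a = c(4, 5, 5.125, 10),
                   stringsAsFactors = FALSE)
  dp <- differentialPeaks(pk, fold = 2, pseudocount = 0.5)
  expect_identical(dp$q_open, "p1")           # (10.5)/(4.5) = 2.33 > 2
  expect_identical(dp$a_open, "p4")
  expect_false("p2" %in% c(dp$q_open, dp$a_open))  # equal concentrations
  expect_false("p3" %in% dp$q_open)           # ratio exactly 2.0 -> strict
  expect_length(intersect(dp$q_open, dp$a_open), 0)
  bad <- pk; bad$conc_q[1] <- 0
  expect_error(differentialPeaks(bad, pseudocount = 0), "pseudocount")
  expect_silent(differentialPeaks(bad, pseudocount = 0.5))
})

test_that("nearest gene uses TSS distance with stated tie-break", {
  genes <- toy_genes()
  # peak spanning G1's TSS (+ strand, TSS = start = 1000)
  nn <- nearestGene(data.frame(id = "p", chrom = "chr1",
                               start = 900L, end = 1100L), genes)
  expect_equal(nn$gene_id, "G1")
  expect_equal(nn$distance_bp, 0L)
  # G2 is - strand: TSS = end - 1 = 5999
  nn2 <- nearestGene(data.frame(id = "p", chrom = "chr1",
                                start = 6100L, end = 6200L), genes)
  expect_equal(nn2$gene_id, "G2")
  expect_equal(nn2$distance_bp, 101L)
  # equidistant -> lexicographically smaller gene id
  g <- data.frame(gene_id = c("GB", "GA"), symbol = c("b", "a"),
                  chrom = "chr1", strand = "+",
                  start = c(2000L, 1000L), end = c(2500L, 1500L),
                  stringsAsFactors = FALSE)
  nn3 <- nearestGene(data.frame(id = "p", chrom = "chr1",
                                start = 1400L, end = 1601L), g)
  expect_equal(nn3$gene_id, "GA")
  # chromosome with no genes -> explicit NA assignment
  nn4 <- nearestGene(data.frame(id = "p", chrom = "chrX",
                                start = 0L, end = 100L), genes)
  expect_true(is.na(nn4$gene_id))
})

test_that("nearest gene equals the exhaustive minimum on random fixtures", {
  set.seed(21)
  genes <- generateGenome(smallConfig(seed = 21))
  for (i in 1:100) {
    st <- sample.int(5e5, 1)
    pk <- data.frame(id = "p", chrom = sample(c("chr1", "chr2"), 1),
                     start = st, end = st + sample(100:1000, 1))
    got <- nearestGene(pk, genes)
    ref <- oracle_nearest(pk, genes)
    expect_identical(got$gene_id, ref$gene)
    expect_equal(got$distance_bp, ref$dist)
  }
})

test_that("regulome calls require all three evidence layers", {
  genes <- toy_genes()
  pk <- data.frame(
    id = c("pA", "pB", "pC", "pD"),
    chrom = "chr1",
    start = c(700L, 800L, 900L, 950L),
    end = c(750L, 850L, 950L, 1000L),
    conc_q = c(10, 10, 10, 10),
    conc_a = c(2, 2, 10, 2),
    stringsAsFactors = FALSE
  )
  ctr <- data.frame(gene_id = c("G1", "G2", "G3"),
                    log2fc = c(log2(1.8), 0, 0),
                    p = c(0.01, 0.9, 0.9), stringsAsFactors = FALSE)
  hm <- c(pA = TRUE, pB = FALSE, pC = TRUE, pD = TRUE)
  calls <- inferRegulome(pk, genes, hm, ctr)
  # pA/pD qualify (motif + fold) and G1 is up 1.8-fold -> repressed, with the
  # closest peak (pD) as support
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene_id, "G1")
  expect_equal(calls$mode, "repressed")
  expect_equal(calls$peak_id, "pD")
  expect_equal(calls$peak_state, "open-in-qHSC")
  # down-regulated gene flips to an activated call
  ctr2 <- ctr; ctr2$log2fc[1] <- -log2(1.8)
  expect_equal(inferRegulome(pk, genes, hm, ctr2)$mode, "activated")
  # motif-free or sub-threshold expression -> no call
  expect_equal(nrow(inferRegulome(pk, genes, c(pA = FALSE, pB = FALSE,
                                               pC = TRUE, pD = FALSE),
                                  ctr)), 0L)
  ctr3 <- ctr; ctr3$log2fc[1] <- log2(1.2)
  expect_equal(nrow(inferRegulome(pk, genes, hm, ctr3)), 0L)
  # optional p gate
  ctr4 <- ctr; ctr4$p[1] <- 0.5
  expect_equal(nrow(inferRegulome(pk, genes, hm, ctr4, p_max = 0.1)), 0L)
})

test_that("id mismatches are reported with the orphan ids", {
  genes <- toy_genes()
  pk <- data.frame(id = "pA", chrom = "chr1", start = 700L, end = 750L,
                   conc_q = 10, conc_a = 2, stringsAsFactors = FALSE)
  ctr <- data.frame(gene_id = "G999", log2fc = 1, p = 0.01,
                    stringsAsFactors = FALSE)
  expect_error(inferRegulome(pk, genes, c(pA = TRUE), ctr), "G1")
  expect_error(inferRegulome(pk, genes, "pZ", ctr), "pZ")
  expect_error(inferRegulome(pk, genes, c(pZ = TRUE), ctr), "pA")
})

test_that("calls are invariant to input row order", {
  study <- simulateRegulomeStudy(smallConfig(seed = 13))
  ctr <- standardContrasts(study$expression)
  hm <- peakHasMotif(study$sequences, eboxPWM())
  base <- inferRegulome(study$peaks, study$genes, hm, ctr$mut_q,
                        ctr$mut_a_t0)
  set.seed(1)
  perm_pk <- study$peaks[sample(nrow(study$peaks)), ]
  perm_gn <- study$genes[sample(nrow(study$genes)), ]
  perm <- inferRegulome(perm_pk, perm_gn, hm, ctr$mut_q, ctr$mut_a_t0)
  rownames(base) <- rownames(perm) <- NULL
  expect_equal(perm, base)
})

test_that("noise-free synthetic data is recovered exactly", {
  cfg <- smallConfig(seed = 17, expression_noise_sd = 0)
  study <- simulateRegulomeStudy(cfg)
  ctr <- standardContrasts(study$expression)
  hm <- peakHasMotif(study$sequences, eboxPWM())
  calls <- inferRegulome(study$peaks, study$genes, hm, ctr$mut_q,
                         ctr$mut_a_t0)
  truth <- study$truth
  expect_setequal(calls$gene_id[calls$mode == "repressed"],
                  repressedGenes(truth))
  expect_setequal(calls$gene_id[calls$mode == "activated"],
                  activatedGenes(truth))
  # each engineered decoy class yields zero calls
  expect_length(intersect(decoyGenes(truth), calls$gene_id), 0)
})
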