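test_that("generators are deterministic and respect genome bounds", {
  cfg <- smallConfig(seed = 7)
  s1 <- simulateRegulomeStudy(cfg)
  s2 <- simulateRegulomeStudy(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(SummarizedExperiment::assay(s1$expression),
                   SummarizedExperiment::assay(s2$expression))
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$cohort, s2$cohort)

  g <- s1$genes
  expect_true(all(g$start >= 0 & g$end <= cfg@chrom_length))
  expect_true(all(g$start < g$end))
  # non-overlapping within a chromosome
  for (ch in split(g, g$chrom)) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1) expect_true(all(ch$start[-1] >= ch$end[-nrow(ch)]))
  }
})

test_that("an unpackable gene count raises a capacity error", {
  cfg <- simulationConfig(seed = 1, n_genes = 50, n_chroms = 1,
                          chrom_length = 2e4, n_peaks = 60,
                          n_planted_repressed = 1, n_planted_activated = 1,
                          n_decoys_per_class = 0)
  expect_error(generateGenome(cfg), "capacity")
})

test_that("planted peaks clear the accessibility filter and decoys do not", {
  study <- simulateRegulomeStudy(smallConfig(seed = 3))
  pk <- study$peaks
  truth <- study$truth
  nn <- nearestGene(pk, study$genes)
  planted_peaks <- nn$peak_id[nn$gene_id %in%
                              c(repressedGenes(truth), activatedGenes(truth))]
  rows <- pk[pk$id %in% planted_peaks & pk$id %in% motifPeaks(truth), ]
  expect_gt(nrow(rows), 0)
  expect_equal(rows$conc_q / rows$conc_a,
               rep(study$config@accessibility_fold, nrow(rows)))
  # no-fold decoy peaks sit at ratio 1 -> filtered out downstream
  dp <- differentialPeaks(pk)
  nofold_peaks <- nn$peak_id[nn$gene_id %in% truth@decoy_no_fold]
  expect_false(any(nofold_peaks %in% dp$q_open))
  # FASTA records and peak rows carry identical id sets
  expect_setequal(names(study$sequences), pk$id)
  expect_true(all(pk$conc_q > 0 & pk$conc_a > 0))
})

test_that("every planted gene's nearest peak carries a motif and q-bias", {
  study <- simulateRegulomeStudy(smallConfig(seed = 5))
  truth <- study$truth
  nn <- nearestGene(study$peaks, study$genes)
  dp <- differentialPeaks(study$peaks)
  for (g in c(repressedGenes(truth), activatedGenes(truth))) {
    pk_ids <- nn$peak_id[nn$gene_id == g]
    expect_true(any(pk_ids %in% motifPeaks(truth) & pk_ids %in% dp$q_open),
                info = g)
  }
})

test_that("noise-free expression carries exactly the planted fold changes", {
  cfg <- smallConfig(seed = 2, expression_noise_sd = 0)
  genes <- generateGenome(cfg)
  truth <- plantGroundTruth(cfg, genes)
  se <- generateExpression(cfg, genes, truth)
  ctr <- expressionContrast(se, "Mut-Q", "WT-Q")
  rep_rows <- ctr[ctr$gene_id %in% repressedGenes(truth), ]
  expect_equal(2^rep_rows$log2fc,
               rep(cfg@expression_fold, nrow(rep_rows)))
  act_rows <- ctr[ctr$gene_id %in% activatedGenes(truth), ]
  expect_equal(2^(-act_rows$log2fc),
               rep(cfg@expression_fold, nrow(act_rows)))
  other <- setdiff(ctr$gene_id,
                   c(repressedGenes(truth), activatedGenes(truth),
                     decoyGenes(truth)))
  expect_equal(ctr$log2fc[ctr$gene_id %in% other],
               rep(0, length(other)))
})

test_that("trace sampling, damping envelope and validation behave", {
  cfg <- simulationConfig(seed = 1)  # 168 h at 10-min sampling
  tr <- generateTrace(cfg)
  expect_equal(nrow(tr), 1009L)  # 168 * 6 + 1, endpoints inclusive
  # noise-free envelope decreases monotonically when damped
  t <- seq(0, 168, by = 1 / 6)
  v <- dampedCosine(t, amplitude = 1, damping = 0.02, period = 24)
  pk <- peakTimes(data.frame(time_h = t, value = v))
  heights <- v[match(pk, t)]
  expect_true(all(diff(heights) < 0))
  expect_error(dampedCosine(1:10, period = -2), "period")
  short <- simulationConfig(seed = 1, trace_duration_h = 60)
  expect_error(generateTrace(short), "3 periods")
})

test_that("cohort generator plants monotone biomarker shifts", {
  cfg <- simulationConfig(seed = 9, cohort_sizes = c(50, 50, 50),
                          cohort_group_shifts = c(0, 5, 20))
  co <- generateCohort(cfg)
  grp <- stratifyPatients(co)
  means <- tapply(co$biomarker, grp, mean)
  expect_true(means[["low"]] < means[["intermediate"]])
  expect_true(means[["intermediate"]] < means[["high"]])
  expect_true(all(co$lsm_kpa[grp == "low"] < 8))
  expect_true(all(co$lsm_kpa[grp == "high"] > 15))
  expect_error(simulationConfig(seed = 1, cohort_sizes = c(0, 10, 10)),
               "group sizes")
})

test_that("gene sets contain the planted term and round-trip through GMT", {
  study <- simulateRegulomeStudy(smallConfig(seed = 4))
  sets <- study$gene_sets
  planted <- sets[[study$truth@enriched_term]]
  overlap <- length(intersect(planted, repressedGenes(study$truth)))
  expect_gte(overlap / length(planted), 0.8)
  expect_true(all(unlist(sets) %in% study$genes$gene_id))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sets, path)
  back <- readGMT(path)
  expect_identical(unclass(back)[names(sets)], lapply(sets, identity))
  expect_identical(attr(back, "descriptions"), attr(sets, "descriptions"))
})

test_that("random gene-set overlap matches the hypergeometric mean", {
  # expected overlap of a random size-K set with a fixed query of size n
  # out of N genes is n*K/N
  set.seed(11)
  N <- 60; n <- 15; K <- 12
  genome <- sprintf("G%04d", 1:N)
  query <- genome[1:n]
  ov <- replicate(3000, length(intersect(sample(genome, K), query)))
  expect_equal(mean(ov), n * K / N, tolerance = 0.05)
})

test_that("all written study files parse with the package readers", {
  study <- simulateRegulomeStudy(smallConfig(seed = 6))
  dir <- withr::local_tempdir()
  writeStudy(study, dir)
  genes <- readGenesTable(file.path(dir, "genes.tsv"))
  expect_identical(genes, study$genes)
  peaks <- readPeaksTable(file.path(dir, "peaks.tsv"))
  expect_equal(peaks, study$peaks, tolerance = 1e-6)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "peaks.fasta"))
  expect_identical(as.character(seqs), as.character(study$sequences))
  se <- readExpressionMatrix(file.path(dir, "expression.csv"))
  expect_equal(SummarizedExperiment::assay(se),
               SummarizedExperiment::assay(study$expression),
               tolerance = 1e-6)
  tr <- readTrace(file.path(dir, "trace.csv"))
  expect_equal(tr, study$trace, tolerance = 1e-6)
  co <- readCohort(file.path(dir, "cohort.csv"))
  expect_equal(co, study$cohort, tolerance = 1e-6)
  truth <- readGroundTruth(file.path(dir, "truth.json"))
  expect_identical(repressedGenes(truth), repressedGenes(study$truth))
  expect_identical(motifPeaks(truth), motifPeaks(study$truth))
})
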