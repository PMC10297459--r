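make_se <- function(mat, cond) {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  }
  repl <- stats::ave(seq_along(cond), cond, FUN = seq_along)
  colnames(mat) <- paste0(cond, "_", repl)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat),
    colData = S4Vectors::DataFrame(condition = cond, replicate = repl,
                                   row.names = colnames(mat)))
}

test_that("contrast arithmetic, t-test and error handling are correct", {
  mat <- rbind(g1 = c(3, 3, 3, 1, 1, 1), g2 = c(2, 2.5, 3, 2, 2.5, 3))
  se <- make_se(mat, rep(c("A", "B"), each = 3))
  ctr <- expressionContrast(se, "A", "B")
  expect_equal(ctr$log2fc, c(2, 0))
  expect_equal(ctr$fold_change[1], 4)
  # p matches stats::t.test with pooled variance
  set.seed(1)
  m2 <- matrix(rnorm(60), nrow = 10)
  se2 <- make_se(m2, rep(c("A", "B"), each = 3))
  ctr2 <- expressionContrast(se2, "A", "B")
  for (i in c(1, 5, 10)) {
    ref <- t.test(m2[i, 1:3], m2[i, 4:6], var.equal = TRUE)$p.value
    expect_equal(ctr2$p[i], ref)
  }
  expect_equal(ctr2$fdr, p.adjust(ctr2$p, "BH"))
  expect_error(expressionContrast(se, "A", "nope"), "unknown condition")
  # identical replicate sets -> log2fc 0 everywhere
  ctr3 <- expressionContrast(make_se(cbind(mat, mat)[, c(1:6, 1:6)],
                                     rep(c("X", "Y"), each = 6)), "X", "Y")
  expect_true(all(ctr3$log2fc == 0))
})

test_that("single-replicate contrasts return fold changes with NA p", {
  mat <- rbind(g1 = c(5, 3), g2 = c(1, 2))
  se <- make_se(mat, c("A", "B"))
  ctr <- expressionContrast(se, "A", "B")
  expect_equal(ctr$log2fc, c(2, -1))
  expect_true(all(is.na(ctr$p)) && all(is.na(ctr$fdr)))
})

test_that("contrasts are antisymmetric in their arguments", {
  set.seed(42)
  se <- make_se(matrix(rnorm(48, 8), nrow = 8),
                rep(c("A", "B"), each = 3))
  ab <- expressionContrast(se, "A", "B")
  ba <- expressionContrast(se, "B", "A")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("direction-pattern clusters place the two characterised patterns", {
  cfg <- smallConfig(seed = 2, expression_noise_sd = 0)
  genes <- generateGenome(cfg)
  truth <- plantGroundTruth(cfg, genes)
  se <- generateExpression(cfg, genes, truth)
  suppressMessages(cl <- assignPatternCluster(standardContrasts(se)))
  # planted repressed genes: up in mutant qHSCs and up on activation -> 4
  expect_true(all(cl$cluster[cl$gene_id %in% repressedGenes(truth)] == 4L))
  # planted activated genes: down in both -> 6
  expect_true(all(cl$cluster[cl$gene_id %in% activatedGenes(truth)] == 6L))
  # untouched genes are flat everywhere -> unassigned
  untouched <- setdiff(genes$gene_id,
                       c(repressedGenes(truth), activatedGenes(truth),
                         decoyGenes(truth)))
  expect_true(all(is.na(cl$cluster[cl$gene_id %in% untouched])))
  # taxonomy covers the full 3x3 grid with the pinned cells
  tax <- clusterTaxonomy()
  expect_equal(nrow(unique(tax[, 2:3])), 9L)
  expect_equal(tax$mutant_direction[tax$cluster == 4], "up")
  expect_equal(tax$activation_direction[tax$cluster == 4], "up")
  expect_equal(tax$mutant_direction[tax$cluster == 6], "down")
  expect_equal(tax$activation_direction[tax$cluster == 6], "down")
  expect_error(assignPatternCluster(list(mut_q = data.frame())),
               "missing contrasts")
})

test_that("primed-gene selection applies strict fold and p thresholds", {
  ctr <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(log2(1.6), log2(1.5), log2(3), -log2(1.6), log2(1.2)),
    p = c(0.05, 0.01, 0.2, 0.05, 0.01),
    stringsAsFactors = FALSE
  )
  sel <- selectPrimedGenes(ctr, fold = 1.5, p_max = 0.1)
  expect_identical(sel$up, "a")       # 1.6-fold, p 0.05 -> in
  expect_identical(sel$down, "d")
  expect_false("b" %in% sel$up)       # exactly 1.5-fold -> excluded
  expect_false("c" %in% sel$up)       # p 0.2 -> excluded
  # noise-free planted repressed genes land exactly in the up list
  cfg <- smallConfig(seed = 8, expression_noise_sd = 0)
  genes <- generateGenome(cfg)
  truth <- plantGroundTruth(cfg, genes)
  ctr2 <- expressionContrast(generateExpression(cfg, genes, truth),
                             "Mut-Q", "WT-Q")
  sel2 <- selectPrimedGenes(ctr2)
  expect_true(all(repressedGenes(truth) %in% sel2$up))
  expect_true(all(activatedGenes(truth) %in% sel2$down))
})
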