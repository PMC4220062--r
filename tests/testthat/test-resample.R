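test_that("resampling picks existing values and is the identity when forced", {
  ## single replicate: only one choice
  re1 <- toyExperiment(nGenes = 3, nRep = 1)
  rs1 <- resampleDataset(re1, seed = 1)
  expect_equal(assay(rs1, "exprs"), assay(re1, "exprs"),
               ignore_attr = TRUE)
  ## identical replicates: output equals replicate 1 regardless of draws
  m <- matrix(rnorm(36), 3)
  re3 <- RhythmExperiment(cbind(m, m, m), time = rep(TP12, 3),
                          replicate = rep(1:3, each = 12))
  rs3 <- resampleDataset(re3, seed = 2)
  expect_equal(assay(rs3, "exprs"), m, ignore_attr = TRUE)
  ## every output value is one of the input values at its cell
  re <- toyExperiment(nGenes = 5, nRep = 3, seed = 7)
  a <- exprsArray(re)
  for (s in 1:5) {
    out <- exprsArray(resampleDataset(re, seed = s))[, , 1]
    for (g in 1:5) for (ti in 1:12)
      expect_true(out[g, ti] %in% a[g, ti, ])
  }
  ## per-sample mode: one replicate choice per timepoint, all genes
  outS <- exprsArray(resampleDataset(re, mode = "per_sample", seed = 3))[, , 1]
  for (ti in 1:12) {
    match_rep <- vapply(1:3, function(r) all(outS[, ti] == a[, ti, r]),
                        logical(1))
    expect_true(any(match_rep))
  }
})

test_that("replicate selection frequencies are uniform (chi-square)", {
  ## 10000 genes x 3 timepoints with replicate-identifying sentinel values
  G <- 10000L
  tp <- c(0, 4, 8)
  vals <- c(1, 2, 3)   # replicate r carries value r everywhere
  m <- cbind(matrix(1, G, 3), matrix(2, G, 3), matrix(3, G, 3))
  re <- RhythmExperiment(m, time = rep(tp, 3), replicate = rep(1:3, each = 3))
  out <- exprsArray(resampleDataset(re, seed = 99))[, , 1]
  draws <- as.vector(out)   # 30000 independent uniform picks
  counts <- table(factor(draws, levels = vals))
  expect_equal(length(draws), 30000L)
  freq <- as.numeric(counts) / length(draws)
  expect_true(all(abs(freq - 1 / 3) <= 0.01))
  chi <- stats::chisq.test(as.numeric(counts))
  expect_gt(chi$p.value, 0.001)
})

test_that("averaging replicates matches the summation oracle", {
  re <- toyExperiment(nGenes = 4, nRep = 3, seed = 12)
  a <- exprsArray(re)
  avg <- exprsArray(averageDataset(re))[, , 1]
  oracle <- (a[, , 1] + a[, , 2] + a[, , 3]) / 3
  expect_equal(avg, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  ## toy cell value
  m <- matrix(c(1, 2, 3), 1)
  re2 <- RhythmExperiment(m, time = rep(0, 3), replicate = 1:3)
  ## 1 timepoint x 3 replicates: mean must be 2
  expect_equal(unname(assay(averageDataset(re2), "exprs")[1, 1]), 2)
  ## single replicate: identity
  re1 <- toyExperiment(nGenes = 2, nRep = 1)
  expect_equal(assay(averageDataset(re1), "exprs"),
               assay(re1, "exprs"), ignore_attr = TRUE)
})

test_that("long-run average of resampled datasets converges to the mean", {
  set.seed(5)
  m <- matrix(runif(12, 1, 3), 2)   # 2 genes x 2 timepoints x 3 replicates
  re <- RhythmExperiment(matrix(m, 2), time = rep(c(0, 4), 3),
                         replicate = rep(1:3, each = 2))
  avg <- exprsArray(averageDataset(re))[, , 1]
  acc <- matrix(0, 2, 2)
  n <- 10000L
  for (i in seq_len(n))
    acc <- acc + exprsArray(resampleDataset(re, seed = i))[, , 1]
  expect_equal(acc / n, avg, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("consensus counting and thresholding follow set semantics", {
  cs <- list(c("A", "B"), "B", c("B", "C"))
  ct <- consensusCounts(cs, universe = c("A", "B", "C", "D"))
  ## enumeration: A in set 1 only, B in all three, C in set 3 only
  expect_equal(geneCounts(ct), c(A = 1L, B = 3L, C = 1L, D = 0L))
  expect_equal(nDatasets(ct), 3L)
  expect_setequal(consensusSet(ct, 1), c("A", "B", "C"))   # union
  expect_equal(consensusSet(ct, 3), "B")                   # intersection
  expect_error(consensusSet(ct, 0), "\\[1, nDatasets\\]")
  expect_error(consensusSet(ct, 4), "\\[1, nDatasets\\]")
  expect_error(consensusCounts(list("Z"), universe = c("A")), "universe")
  ## empty list: all counts zero
  ct0 <- consensusCounts(list(), universe = c("A", "B"))
  expect_true(all(geneCounts(ct0) == 0L))
  ## full membership
  ct36 <- consensusCounts(rep(list("A"), 36), universe = "A")
  expect_equal(unname(geneCounts(ct36)), 36L)
})

test_that("consensus sets are nested decreasing in k", {
  set.seed(17)
  universe <- paste0("g", 1:40)
  for (rep in 1:5) {
    cs <- lapply(1:6, function(i) sample(universe, sample(0:30, 1)))
    ct <- consensusCounts(cs, universe)
    for (k in 1:5)
      expect_true(all(consensusSet(ct, k + 1) %in% consensusSet(ct, k)))
    ## k = 1 is the union
    expect_setequal(consensusSet(ct, 1), unique(unlist(cs)))
  }
})

test_that("the resampling analysis returns seeded, reproducible call sets", {
  ## strong rhythms only: every resample must call every gene
  X <- t(vapply(seq(22, 28, length.out = 10), function(tt)
    cosineRow(TP12, 4, tt), numeric(12)))
  rownames(X) <- paste0("g", 1:10)
  re <- RhythmExperiment(cbind(X, X, X), time = rep(TP12, 3),
                         replicate = rep(1:3, each = 12))
  ra <- runResamplingAnalysis(re, method = "arser", nResamples = 5,
                              seed = 42)
  expect_length(ra$callSets, 5)
  expect_true(all(geneCounts(ra$consensus) == 5L))
  ## determinism under a fixed seed
  ra2 <- runResamplingAnalysis(re, method = "arser", nResamples = 5,
                               seed = 42)
  expect_identical(geneCounts(ra$consensus), geneCounts(ra2$consensus))
  expect_identical(ra$manifest$subSeeds, ra2$manifest$subSeeds)
  ra3 <- runResamplingAnalysis(re, method = "arser", nResamples = 5,
                               seed = 43)
  expect_false(identical(ra$manifest$subSeeds, ra3$manifest$subSeeds))
})
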