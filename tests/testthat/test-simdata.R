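test_that("LD simulation evaluates the cosine model exactly and carries labels", {
  ## fixed period/phase, no noise: rows must equal the analytic cosine
  coh <- simulateLD(nRhythmic = 3, nNull = 2, nIndividuals = 2,
                    noiseSd = 0, periodRange = c(24, 24),
                    phaseGrid = c(0, 0, 0.1), seed = 1)
  m <- individualMatrix(coh, 1)
  expected <- cosineRow(TP12, amplitude = 4, period = 24, phase = 0)
  for (g in 1:3) expect_equal(unname(m[g, ]), expected, tolerance = 1e-12)
  expect_equal(unname(m[1, 1]), 4)           # SNR*2*cos(0) at t = 0
  ## sample variance over full cycles equals (SNR*2)^2 / 2
  expect_equal(mean(m[1, ]^2) - mean(m[1, ])^2, 4^2 / 2, tolerance = 1e-9)
  ## null rows are exactly zero without noise
  expect_true(all(m[4:5, ] == 0))
  ## labels
  tl <- truthLabels(coh)
  expect_equal(sum(tl), 3)
  expect_equal(sum(!tl), 2)
  expect_true(all(is.na(geneParams(coh)$period[4:5])))
  ## amplitude override
  coh2 <- simulateLD(nRhythmic = 1, nNull = 0, nIndividuals = 1,
                     noiseSd = 0, periodRange = c(24, 24),
                     phaseGrid = c(0, 0, 0.1), amplitude = 1, seed = 1)
  expect_equal(max(abs(individualMatrix(coh2, 1))), 1, tolerance = 1e-12)
})

test_that("LD cohorts are synchronised, deterministic, and validate input", {
  coh <- simulateLD(nRhythmic = 5, nNull = 5, nIndividuals = 3,
                    noiseSd = 0, seed = 3)
  ## synchrony: with zero noise all individuals coincide
  expect_identical(individualMatrix(coh, 1), individualMatrix(coh, 2))
  expect_identical(individualMatrix(coh, 2), individualMatrix(coh, 3))
  ## determinism: identical seed and config give bit-identical datasets
  cohA <- simulateLD(nRhythmic = 4, nNull = 4, nIndividuals = 2, seed = 9)
  cohB <- simulateLD(nRhythmic = 4, nNull = 4, nIndividuals = 2, seed = 9)
  expect_identical(cohA@values, cohB@values)
  cohC <- simulateLD(nRhythmic = 4, nNull = 4, nIndividuals = 2, seed = 10)
  expect_false(identical(cohA@values, cohC@values))
  ## period/phase draws respect their supports
  gp <- geneParams(cohA)
  expect_true(all(gp$period[1:4] >= 22 & gp$period[1:4] <= 28))
  expect_true(all(gp$phase[1:4] %in% seq(0, 28, by = 0.1)))
  ## invalid configurations
  expect_error(simulateLD(nRhythmic = 0, nNull = 2), "counts")
  expect_error(simulateLD(nRhythmic = 2, timepoints = c(4, 0, 8)),
               "increasing")
  expect_error(simulateLD(nRhythmic = 2, nNull = 2, noiseSd = -1),
               "noiseSd")
})

test_that("LL simulation draws per-individual free-running periods", {
  ## degenerate sd: all individuals share the 25 h period, synchronised
  coh0 <- simulateLL(nRhythmic = 3, nNull = 1, nIndividuals = 3,
                     noiseSd = 0, llPeriodSd = 0, seed = 2)
  expect_true(all(individualPeriods(coh0) == 25))
  expect_identical(individualMatrix(coh0, 1), individualMatrix(coh0, 3))
  gp <- geneParams(coh0)
  expect_equal(unname(individualMatrix(coh0, 1)[1, ]),
               cosineRow(TP12, 4, 25, gp$phase[1]), tolerance = 1e-12)
  ## default: 36 distinct periods, mean within 3 standard errors of 25
  coh <- simulateLL(nRhythmic = 2, nNull = 2, nIndividuals = 36, seed = 5)
  tau <- individualPeriods(coh)
  expect_equal(length(unique(tau)), 36)
  expect_lt(abs(mean(tau) - 25), 3 * 3 / sqrt(36))
  expect_true(all(tau >= 10))
  ## desynchrony: noiseless rhythmic rows are not perfectly correlated
  cohd <- simulateLL(nRhythmic = 3, nNull = 0, nIndividuals = 4,
                     noiseSd = 0, seed = 6)
  r12 <- cor(individualMatrix(cohd, 1)[1, ], individualMatrix(cohd, 2)[1, ])
  expect_lt(r12, 1 - 1e-6)
})

test_that("white-noise null profiles have the requested moments", {
  expect_true(all(simulateNull(4, TP12, mean = 7, sd = 0) == 7))
  m <- simulateNull(8400, TP12, mean = 0, sd = 1, seed = 11)
  expect_equal(dim(m), c(8400, 12))
  ## CLT bound at 4 standard errors
  expect_lt(abs(mean(m)), 4 / sqrt(8400 * 12))
  expect_error(simulateNull(5, TP12, sd = -1), "non-negative")
})

test_that("ODE-based simulation produces periodic standardised waveforms", {
  osc <- goodwinOscillator()
  cyc <- oscillatorCycle(osc)
  expect_gt(cyc$period, 23)
  expect_lt(cyc$period, 25)
  ## periodicity of the extracted cycle
  u <- seq(0, 10, by = 0.5)
  expect_equal(cyc$cycle("X", u), cyc$cycle("X", u + cyc$period),
               tolerance = 1e-3)
  coh <- simulateODE(nRhythmic = 6, nNull = 2, nIndividuals = 2,
                     noiseSd = 0, seed = 4)
  m <- individualMatrix(coh, 1)
  gp <- geneParams(coh)
  ## noiseless rows reproduce the standardised, shifted species trajectory
  u2 <- seq(0, cyc$period, length.out = 2048L)[-2048L]
  for (g in c(1, 2)) {
    s <- gp$waveform[g]
    v <- cyc$cycle(s, u2)
    expected <- (cyc$cycle(s, (TP12 - gp$phase[g]) %% cyc$period) -
                   mean(v)) / sd(v) * 4
    expect_equal(unname(m[g, ]), expected, tolerance = 1e-6)
  }
  ## species assigned cyclically over the gene list
  expect_equal(gp$waveform[1:6], rep(c("X", "Y", "Z"), 2))
  ## a non-oscillating system is reported as such
  dud <- goodwinOscillator(production = 0.3, degradation = 0.15)
  expect_error(oscillatorCycle(dud), "periodic orbit|settled")
})

test_that("initial-dataset assembly is injective and uses each individual once", {
  coh <- simulateLD(nRhythmic = 4, nNull = 4, nIndividuals = 36, seed = 21)
  re <- assembleInitialDatasets(coh, nReplicates = 3, seed = 22)
  prov <- provenance(re)
  ## 36 slots, each individual used exactly once
  expect_equal(nrow(prov), 36)
  expect_equal(sort(prov$individual), 1:36)
  ## every value traceable to its individual
  a <- exprsArray(re)
  tp <- timepoints(re)
  for (i in sample(nrow(prov), 10)) {
    ti <- match(prov$time[i], tp)
    expect_equal(a[, ti, prov$replicate[i]],
                 coh@values[, ti, prov$individual[i]],
                 ignore_attr = TRUE)
  }
  ## 72 individuals, 2 replicates: exactly 24 used, 48 unused
  coh72 <- simulateLD(nRhythmic = 2, nNull = 2, nIndividuals = 72, seed = 23)
  re2 <- assembleInitialDatasets(coh72, nReplicates = 2, seed = 24)
  used <- unique(provenance(re2)$individual)
  expect_equal(length(used), 24)
  ## single replicate of 12 individuals: a permutation column-map
  coh12 <- simulateLD(nRhythmic = 3, nNull = 0, nIndividuals = 12, seed = 25)
  re1 <- assembleInitialDatasets(coh12, nReplicates = 1, seed = 26)
  p1 <- provenance(re1)
  expect_equal(sort(unique(p1$individual)), sort(p1$individual))
  for (i in seq_len(nrow(p1))) {
    ti <- match(p1$time[i], timepoints(re1))
    expect_equal(exprsArray(re1)[, ti, 1],
                 coh12@values[, ti, p1$individual[i]], ignore_attr = TRUE)
  }
  ## too few individuals is an error stating the requirement
  expect_error(assembleInitialDatasets(coh12, nReplicates = 2), "24")
})
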