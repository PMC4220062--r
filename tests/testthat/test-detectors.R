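test_that("linear detrending matches the closed-form least-squares solution", {
  t5 <- c(0, 4, 8, 12, 16)
  expect_equal(linearDetrend(2 * t5 + 5, t5), rep(0, 5), tolerance = 1e-10)
  expect_equal(linearDetrend(rep(3.3, 5), t5), rep(0, 5), tolerance = 1e-12)
  ## normal-equation oracle on an arbitrary series
  y <- c(1, 4, 2, 8, 5)
  X <- cbind(1, t5)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(linearDetrend(y, t5), as.numeric(y - X %*% beta),
               tolerance = 1e-10)
  ## residuals orthogonal to both regressors
  r <- linearDetrend(y, t5)
  expect_lt(abs(sum(r)), 1e-10)
  expect_lt(abs(sum(r * t5)), 1e-9)
  expect_error(linearDetrend(c(1, 2), c(0, 4)), "length")
})

test_that("AR spectral candidates locate in-band periods (periodogram oracle)", {
  y24 <- cosineRow(TP12, period = 24)
  cand <- arSpectralPeriods(y24, TP12)
  expect_gt(length(cand), 0)
  expect_lt(min(abs(cand - 24)), 0.5)
  ## agreement with the independent Schuster periodogram maximum
  oracle <- periodogramPeakPeriod(y24, TP12)
  expect_lt(min(abs(cand - oracle)), 0.5)
  ## a 12 h rhythm (outside the band, oracle-confirmed) yields no candidate
  y12 <- cosineRow(TP12, period = 12)
  expect_lt(abs(periodogramPeakPeriod(y12, TP12) - 12), 0.5)
  expect_length(arSpectralPeriods(y12, TP12), 0)
  ## flat series: flat spectrum, no candidates
  expect_length(arSpectralPeriods(rep(0, 12), TP12), 0)
  expect_error(arSpectralPeriods(rnorm(5), c(0, 1, 3, 7, 8)), "uniform")
})

test_that("harmonic regression recovers cyclic parameters and matches OLS oracle", {
  y <- 3 + 4 * cos(2 * pi * TP12 / 24)
  fit <- harmonicRegression(y, TP12, periods = 24)
  expect_equal(fit$amplitude, 4, tolerance = 1e-8)
  expect_equal(fit$meanLevel, 3, tolerance = 1e-8)
  expect_lt(min(fit$phase, 24 - fit$phase), 1e-8)
  expect_lt(fit$pvalue, 1e-12)
  ## phase parameter maps back to the generating phase
  y2 <- cosineRow(TP12, amplitude = 2, period = 24, phase = 7)
  expect_equal(harmonicRegression(y2, TP12, 24)$phase, 7, tolerance = 1e-8)
  ## coefficients equal the independent normal-equation solution
  set.seed(8)
  yr <- rnorm(12)
  X <- cbind(1, cos(2 * pi * TP12 / 24), sin(2 * pi * TP12 / 24))
  beta <- solve(t(X) %*% X, t(X) %*% yr)
  fitR <- harmonicRegression(yr, TP12, 24)
  expect_equal(unname(fitR$coefficients), as.numeric(beta),
               tolerance = 1e-9)
  ## AIC selection picks the better of two candidate periods
  y25 <- cosineRow(TP12, period = 25)
  expect_equal(harmonicRegression(y25, TP12, c(21, 25))$period, 25)
  expect_error(harmonicRegression(yr, TP12, numeric(0)), "non-empty")
})

test_that("harmonic-regression p-values are uniform under the Gaussian null", {
  set.seed(13)
  p <- vapply(seq_len(2000), function(i)
    harmonicRegression(rnorm(12), TP12, 24)$pvalue, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("Benjamini-Hochberg q-values match the hand-computed step-up", {
  expect_equal(bhFDR(0.03), 0.03)
  ## min over j >= i of m p_(j) / j = 0.04 at every rank here
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(rep(0.5, 7)), rep(0.5, 7))
  ## permutation equivariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bhFDR(p)[perm], bhFDR(p[perm]))
  expect_error(bhFDR(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhFDR(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("ARSER pipeline separates clean rhythms from flat and noise genes", {
  set.seed(31)
  tau <- runif(50, 22, 28)
  X <- rbind(t(vapply(tau, function(tt) cosineRow(TP12, 4, tt,
                                                  runif(1, 0, 24)),
                      numeric(12))),
             matrix(0, 50, 12))
  r <- arserDetect(X, TP12)
  expect_true(all(r$rhythmic[1:50]))
  expect_true(all(!r$rhythmic[51:100]))
  expect_true(all(r$flagged[51:100]))
  ## estimated periods track the generating periods
  expect_lt(max(abs(r$period[1:50] - tau)), 0.5)
  ## q-values come from the BH step-up over the whole dataset
  expect_equal(r$qvalue, bhFDR(r$pvalue))
})

test_that("ARSER results are deterministic and nearly exact on noiseless input", {
  y25 <- cosineRow(TP12, amplitude = 4, period = 25, phase = 3, mesor = 2)
  r1 <- arserDetect(rbind(a = y25), TP12)
  expect_equal(r1$period, 25, tolerance = 1e-6)
  expect_equal(r1$amplitude, 4, tolerance = 1e-6)
  expect_equal(r1$phase, 3, tolerance = 1e-5)
  expect_equal(r1$meanLevel, 2, tolerance = 1e-6)
  r2 <- arserDetect(rbind(a = y25), TP12)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("pattern library covers the named shapes with valid templates", {
  lib <- suppressWarnings(buildPatternLibrary(TP12))
  ## 6 shapes x 24 phases minus grid-degenerate spike templates
  expect_equal(length(lib), 6 * 24 - 18)
  expect_setequal(unique(lib@shape),
                  c("asymmetric", "box", "cosine", "rigid", "sine",
                    "spike"))
  ## all templates centred and unit-norm (class validity)
  expect_true(validObject(lib))
  ## cosine at phase 0 is proportional to cos(2 pi t / 24)
  i <- which(lib@shape == "cosine" & lib@phaseShift == 0)
  v <- cos(2 * pi * TP12 / 24)
  expect_equal(lib@templates[i, ], v / sqrt(sum(v^2)), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## quadrature identity: sine at phase 0 equals cosine at phase 6 h
  j <- which(lib@shape == "sine" & lib@phaseShift == 0)
  k <- which(lib@shape == "cosine" & lib@phaseShift == 6)
  expect_equal(lib@templates[j, ], lib@templates[k, ], tolerance = 1e-10)
  ## degenerate templates raise a warning
  expect_warning(buildPatternLibrary(TP12, shapes = "spike"), "degenerate")
})

test_that("HAYSTACK correlation is affine-invariant and matches enumeration", {
  lib <- suppressWarnings(buildPatternLibrary(TP12))
  ## gene equal to a template up to offset and positive scale: r = 1.
  ## cosine at phase 2 coincides with sine at phase 20; the tie-break
  ## rule (lowest phase shift first) must pick the cosine
  i <- which(lib@shape == "cosine" & lib@phaseShift == 2)
  g <- 10 + 3.7 * lib@templates[i, ]
  r <- haystackDetect(rbind(g = g), TP12, library = lib)
  expect_equal(unname(r$correlation), 1, tolerance = 1e-10)
  expect_equal(r$bestPattern, "cosine")
  expect_equal(r$phase, 2)
  ## constant positive gene: fold change 1, not rhythmic
  rc <- haystackDetect(rbind(g = rep(5, 12)), TP12, library = lib)
  expect_equal(unname(rc$foldChange), 1)
  expect_false(rc$rhythmic)
  expect_true(rc$flagged)
  ## brute-force enumeration oracle for the best correlation
  set.seed(77)
  gene <- rnorm(12)
  small <- suppressWarnings(
    buildPatternLibrary(TP12, shapes = c("cosine", "box"), phaseStep = 8))
  rs <- haystackDetect(rbind(g = gene), TP12, library = small)
  oracle <- apply(small@templates, 1, function(tmpl) cor(gene, tmpl))
  expect_equal(unname(rs$correlation), max(oracle), tolerance = 1e-10)
  best <- which(abs(oracle - max(oracle)) < 1e-12)[1]
  expect_equal(rs$bestPattern, small@shape[best])
})

test_that("HAYSTACK applies all four cutoffs", {
  lib <- suppressWarnings(buildPatternLibrary(TP12))
  i <- which(lib@shape == "cosine" & lib@phaseShift == 0)
  strong <- 5 + 4 * lib@templates[i, ] * sqrt(12)   # high fold, r = 1
  weak <- 5 + 0.001 * lib@templates[i, ]            # r = 1, fold ~ 1
  r <- haystackDetect(rbind(strong = strong, weak = weak), TP12,
                      library = lib)
  expect_true(r["strong", "rhythmic"])
  expect_false(r["weak", "rhythmic"])   # fails the fold-change cutoff
  expect_gte(r["weak", "correlation"], 0.8)
})

test_that("FFT-NLLS recovers exact cosines and respects the period bounds", {
  y <- cosineRow(TP12, amplitude = 4, period = 24)
  r <- fftnllsDetect(rbind(g = y), TP12)
  expect_equal(r$period, 24, tolerance = 1e-6)
  expect_equal(r$amplitude, 4, tolerance = 1e-6)
  expect_lt(min(r$phase, 24 - r$phase), 1e-6)
  expect_lt(r$rae, 1e-6)
  expect_true(r$rhythmic)
  ## out-of-band rhythm: estimate pinned inside [20, 28]
  y30 <- cosineRow(TP12, amplitude = 4, period = 30)
  r30 <- fftnllsDetect(rbind(g = y30), TP12)
  if (!r30$flagged) {
    expect_gte(r30$period, 20)
    expect_lte(r30$period, 28)
  }
  ## degenerate gene flagged
  rz <- fftnllsDetect(rbind(g = rep(1, 12)), TP12)
  expect_true(rz$flagged)
  expect_false(rz$rhythmic)
})

test_that("FFT-NLLS false-positive fraction on pure noise is small", {
  set.seed(55)
  X <- matrix(rnorm(800 * 12), 800)
  r <- fftnllsDetect(X, TP12)
  expect_lt(mean(r$rhythmic), 0.05)
})

test_that("detectRhythms dispatches and refuses multi-replicate input", {
  re <- toyExperiment(nGenes = 4, nRep = 2)
  expect_error(detectRhythms(re, method = "arser"), "single-replicate")
  one <- replicateExperiment(re, 1)
  r <- detectRhythms(one, method = "arser")
  expect_s4_class(r, "DataFrame")
  expect_equal(rownames(r), rownames(re))
  ## matrix interface agrees with the experiment interface
  m <- assay(one, "exprs")
  r2 <- detectRhythms(m, method = "arser", times = sampleTimes(one))
  expect_equal(as.data.frame(r), as.data.frame(r2))
})
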