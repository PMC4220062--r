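## shared fixtures: everything is generated in code at test time

suppressPackageStartupMessages(library(SummarizedExperiment))

TP12 <- seq(0, 44, by = 4)   # default sampling design: 12 x 4 h

cosineRow <- function(times, amplitude = 4, period = 24, phase = 0,
                      mesor = 0) {
  mesor + amplitude * cos(2 * pi / period * (times - phase))
}

## small replicated experiment with known values
toyExperiment <- function(nGenes = 6, nRep = 3, times = TP12, seed = 42,
                          truth = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * length(times) * nRep), nGenes)
  RhythmExperiment(m, time = rep(times, nRep),
                   replicate = rep(seq_len(nRep), each = length(times)),
                   truth = truth)
}

## confusion counts of a single call set against named truth labels
confusionFromSetForTest <- function(set, truth) {
  pos <- names(truth)[truth]
  neg <- names(truth)[!truth]
  tp <- sum(set %in% pos)
  fp <- sum(set %in% neg)
  c(tp = tp, fp = fp, tn = length(neg) - fp, fn = length(pos) - tp)
}

## independent Schuster periodogram oracle: power at a dense period grid
periodogramPeakPeriod <- function(series, times, periods = seq(8, 96, by = 0.01)) {
  pw <- vapply(periods, function(tau) {
    w <- 2 * pi / tau
    sum(series * cos(w * times))^2 + sum(series * sin(w * times))^2
  }, numeric(1))
  periods[which.max(pw)]
}
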