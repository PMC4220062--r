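## Synthetic circadian time-course generators.
##
## All three rhythmic generators share the same sampling design: G genes
## observed at the same timepoints in each of N individuals, with i.i.d.
## Normal(0, noiseSd) measurement/biological noise per (gene, timepoint,
## individual) and pure-noise null genes appended after the rhythmic block.

DEFAULT_TIMEPOINTS <- seq(0, 44, by = 4)

checkSimArgs <- function(nRhythmic, nNull, timepoints, nIndividuals,
                         noiseSd) {
  if (nRhythmic < 1 || nNull < 0)
    stop("gene counts must be positive (nRhythmic >= 1, nNull >= 0)")
  if (length(timepoints) < 3L || is.unsorted(timepoints, strictly = TRUE))
    stop("'timepoints' must be a strictly increasing vector of >= 3 times")
  if (nIndividuals < 1) stop("'nIndividuals' must be >= 1")
  if (noiseSd < 0) stop("'noiseSd' must be non-negative")
}

phaseGridValues <- function(phaseGrid) {
  if (length(phaseGrid) != 3L || phaseGrid[3] <= 0)
    stop("'phaseGrid' must be c(low, high, step) with step > 0")
  if (phaseGrid[2] < phaseGrid[1]) stop("phase grid low must be <= high")
  seq(phaseGrid[1], phaseGrid[2], by = phaseGrid[3])
}

makeGeneParams <- function(nRhythmic, nNull, period, phase, waveform) {
  g <- nRhythmic + nNull
  S4Vectors::DataFrame(
    class = rep(c("rhythmic", "null"), c(nRhythmic, nNull)),
    period = c(period, rep(NA_real_, nNull)),
    phase = c(phase, rep(NA_real_, nNull)),
    waveform = c(waveform, rep("noise", nNull)),
    row.names = sprintf("gene_%05d", seq_len(g)))
}

newCohort <- function(values, timepoints, geneParams, individualPeriods,
                      mode, seed) {
  dimnames(values) <- list(rownames(geneParams),
                           paste0("T", timepoints), NULL)
  new("SimulatedCohort", values = values, timepoints = as.numeric(timepoints),
      geneParams = geneParams,
      individualPeriods = as.numeric(individualPeriods), mode = mode,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Simulate an entrained (LD) cohort of individual time courses
#'
#' Every rhythmic gene follows
#' \deqn{x_t = \mathrm{SNR}\cdot 2\cos\left(\frac{2\pi}{\tau}(t-\varphi)\right) + \varepsilon_t,}
#' with one period \eqn{\tau} drawn uniformly from `periodRange` and one
#' phase \eqn{\varphi} drawn uniformly from the phase grid per gene,
#' shared across all individuals (a synchronised, entrained population);
#' \eqn{\varepsilon_t \sim N(0, \mathrm{noiseSd})} independently per
#' (gene, timepoint, individual). Null genes are pure
#' \eqn{N(0, \mathrm{noiseSd})} noise.
#'
#' @param nRhythmic,nNull number of rhythmic and null (non-rhythmic) genes.
#' @param timepoints sampling times in hours (default 12 points, 4 h
#'   apart, spanning 48 h).
#' @param nIndividuals number of simulated individuals (independent noisy
#'   copies of the cohort).
#' @param snr signal-to-noise ratio of the cosine model.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param periodRange low/high of the uniform period distribution (hours).
#' @param phaseGrid `c(low, high, step)` in hours; phases are drawn
#'   uniformly from this grid (values beyond one period wrap).
#' @param amplitude overrides the `snr * 2` cosine amplitude when given.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A [SimulatedCohort-class].
#' @examples
#' coh <- simulateLD(nRhythmic = 5, nNull = 5, nIndividuals = 3, seed = 1)
#' dim(individualMatrix(coh, 1))
#' @seealso [simulateLL()], [simulateODE()], [assembleInitialDatasets()]
#' @export
simulateLD <- function(nRhythmic = 8400, nNull = 8400,
                       timepoints = DEFAULT_TIMEPOINTS, nIndividuals = 36,
                       snr = 2, noiseSd = 1, periodRange = c(22, 28),
                       phaseGrid = c(0, 28, 0.1), amplitude = NULL,
                       seed = NULL) {
  checkSimArgs(nRhythmic, nNull, timepoints, nIndividuals, noiseSd)
  if (periodRange[1] > periodRange[2] || periodRange[1] <= 0)
    stop("'periodRange' must satisfy 0 < low <= high")
  A <- if (is.null(amplitude)) snr * 2 else amplitude
  grid <- phaseGridValues(phaseGrid)
  withSeed(seed, {
    tau <- runif(nRhythmic, periodRange[1], periodRange[2])
    phi <- grid[sample.int(length(grid), nRhythmic, replace = TRUE)]
    sig <- A * cos(sweep(outer(2 * pi / tau, timepoints), 1,
                         2 * pi * phi / tau, "-"))
    G <- nRhythmic + nNull
    base <- rbind(sig, matrix(0, nNull, length(timepoints)))
    values <- array(0, dim = c(G, length(timepoints), nIndividuals))
    for (i in seq_len(nIndividuals))
      values[, , i] <- base +
        if (noiseSd > 0) matrix(rnorm(G * length(timepoints), 0, noiseSd),
                                G) else 0
    newCohort(values, timepoints,
              makeGeneParams(nRhythmic, nNull, tau, phi,
                             rep("cosine", nRhythmic)),
              rep(NA_real_, nIndividuals), "ld", seed)
  })
}

#' Simulate a free-running (LL) cohort with desynchronising individuals
#'
#' Same cosine model as [simulateLD()], but each individual draws one
#' free-running period from `Normal(llPeriodMean, llPeriodSd)` (truncated
#' below at `periodFloor` by redrawing) which is shared by all rhythmic
#' genes of that individual, so individuals drift out of phase with one
#' another, as under constant conditions. Per-gene phases are drawn once
#' from the phase grid and shared across individuals.
#'
#' @inheritParams simulateLD
#' @param llPeriodMean,llPeriodSd mean and standard deviation (hours) of
#'   the free-running period distribution. `llPeriodSd = 0` degenerates to
#'   a synchronised cohort with period `llPeriodMean`.
#' @param periodFloor redraw threshold protecting against non-physical
#'   near-zero or negative periods (truncation probability ~3e-7 at the
#'   defaults).
#' @return A [SimulatedCohort-class]; `individualPeriods()` returns the
#'   per-individual periods.
#' @export
simulateLL <- function(nRhythmic = 8400, nNull = 8400,
                       timepoints = DEFAULT_TIMEPOINTS, nIndividuals = 36,
                       snr = 2, noiseSd = 1, llPeriodMean = 25,
                       llPeriodSd = 3, phaseGrid = c(0, 28, 0.1),
                       periodFloor = 10, amplitude = NULL, seed = NULL) {
  checkSimArgs(nRhythmic, nNull, timepoints, nIndividuals, noiseSd)
  if (llPeriodSd < 0) stop("'llPeriodSd' must be non-negative")
  A <- if (is.null(amplitude)) snr * 2 else amplitude
  grid <- phaseGridValues(phaseGrid)
  withSeed(seed, {
    tauInd <- numeric(nIndividuals)
    for (i in seq_len(nIndividuals)) {
      repeat {
        tt <- rnorm(1, llPeriodMean, llPeriodSd)
        if (tt >= periodFloor) break
      }
      tauInd[i] <- tt
    }
    phi <- grid[sample.int(length(grid), nRhythmic, replace = TRUE)]
    G <- nRhythmic + nNull
    values <- array(0, dim = c(G, length(timepoints), nIndividuals))
    for (i in seq_len(nIndividuals)) {
      w <- 2 * pi / tauInd[i]
      sig <- A * cos(w * outer(-phi, timepoints, "+"))
      values[, , i] <- rbind(sig, matrix(0, nNull, length(timepoints))) +
        if (noiseSd > 0) matrix(rnorm(G * length(timepoints), 0, noiseSd),
                                G) else 0
    }
    newCohort(values, timepoints,
              makeGeneParams(nRhythmic, nNull, rep(NA_real_, nRhythmic),
                             phi, rep("cosine", nRhythmic)),
              tauInd, "ll", seed)
  })
}

#' Simulate a cohort from a limit-cycle oscillator
#'
#' Integrates `oscillator` past its transient, extracts one full limit
#' cycle per model species, z-scores each species trajectory over the
#' cycle and scales it to amplitude `snr * 2` so that `Normal(0, noiseSd)`
#' noise yields the same nominal signal-to-noise ratio as the cosine
#' simulations. Each rhythmic gene is one (species, phase shift)
#' combination: species are assigned cyclically and phase shifts are
#' drawn uniformly from a `phaseStep`-spaced grid covering one period.
#' All individuals share the waveforms (synchronised population) and
#' differ only in noise.
#'
#' @inheritParams simulateLD
#' @param oscillator an oscillator description (see [goodwinOscillator()]).
#' @param phaseStep spacing (hours) of the phase-shift grid.
#' @return A [SimulatedCohort-class].
#' @export
simulateODE <- function(nRhythmic = 8400, nNull = 8400,
                        timepoints = DEFAULT_TIMEPOINTS, nIndividuals = 36,
                        snr = 2, noiseSd = 1, phaseStep = 0.1,
                        oscillator = goodwinOscillator(), seed = NULL) {
  checkSimArgs(nRhythmic, nNull, timepoints, nIndividuals, noiseSd)
  cyc <- oscillatorCycle(oscillator)
  P <- cyc$period
  nsp <- length(cyc$species)
  ## standardisation constants over one cycle, per species
  u <- seq(0, P, length.out = 2048L)[-2048L]
  std <- lapply(cyc$species, function(s) {
    v <- cyc$cycle(s, u)
    list(mean = mean(v), sd = sd(v))
  })
  names(std) <- cyc$species
  A <- snr * 2
  grid <- seq(0, P - 1e-9, by = phaseStep)
  withSeed(seed, {
    species <- cyc$species[((seq_len(nRhythmic) - 1L) %% nsp) + 1L]
    shift <- grid[sample.int(length(grid), nRhythmic, replace = TRUE)]
    sig <- matrix(0, nRhythmic, length(timepoints))
    for (s in cyc$species) {
      idx <- which(species == s)
      if (!length(idx)) next
      ph <- outer(-shift[idx], timepoints, "+") %% P
      sig[idx, ] <- (matrix(cyc$cycle(s, as.vector(ph)), length(idx)) -
                       std[[s]]$mean) / std[[s]]$sd * A
    }
    G <- nRhythmic + nNull
    values <- array(0, dim = c(G, length(timepoints), nIndividuals))
    base <- rbind(sig, matrix(0, nNull, length(timepoints)))
    for (i in seq_len(nIndividuals))
      values[, , i] <- base +
        if (noiseSd > 0) matrix(rnorm(G * length(timepoints), 0, noiseSd),
                                G) else 0
    newCohort(values, timepoints,
              makeGeneParams(nRhythmic, nNull, rep(P, nRhythmic), shift,
                             species),
              rep(NA_real_, nIndividuals), "ode", seed)
  })
}

#' Simulate non-rhythmic (white noise) expression profiles
#'
#' @param nNull number of profiles.
#' @param timepoints sampling times (hours).
#' @param mean,sd parameters of the i.i.d. Gaussian values (matching the
#'   noise term of the rhythmic simulations by default).
#' @param seed integer seed.
#' @return numeric matrix, `nNull` x `length(timepoints)`.
#' @export
simulateNull <- function(nNull, timepoints = DEFAULT_TIMEPOINTS, mean = 0,
                         sd = 1, seed = NULL) {
  if (sd < 0) stop("'sd' must be non-negative")
  if (nNull < 1) stop("'nNull' must be >= 1")
  withSeed(seed, {
    m <- matrix(rnorm(nNull * length(timepoints), mean, sd), nNull,
                dimnames = list(sprintf("gene_%05d", seq_len(nNull)),
                                paste0("T", timepoints)))
    m
  })
}

#' Assemble replicate datasets by destructive sampling of individuals
#'
#' Mimics a real time-course experiment in which every sample is a
#' different organism: each (timepoint, replicate) slot of the output is
#' filled from a distinct simulated individual's value at that timepoint
#' (a random injective assignment; when more individuals are available
#' than slots, a random subset is used). The slot-to-individual map is
#' recorded as provenance.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param nReplicates number of replicate time courses to assemble.
#' @param seed integer seed.
#' @return A [RhythmExperiment-class] with `nReplicates` replicates,
#'   per-gene truth in `rowData` and the provenance map in `metadata`.
#' @examples
#' coh <- simulateLD(nRhythmic = 4, nNull = 4, nIndividuals = 36, seed = 1)
#' re <- assembleInitialDatasets(coh, nReplicates = 3, seed = 2)
#' nrow(provenance(re))  # 36 slots, 36 distinct individuals
#' @export
assembleInitialDatasets <- function(cohort, nReplicates = 3, seed = NULL) {
  stopifnot(is(cohort, "SimulatedCohort"))
  tp <- timepoints(cohort)
  nT <- length(tp)
  need <- nReplicates * nT
  N <- nIndividuals(cohort)
  if (N < need)
    stop("too few individuals: ", need, " (timepoints x replicates) ",
         "required but cohort has ", N)
  withSeed(seed, {
    chosen <- sample.int(N, need)          # injective slot assignment
    slot <- matrix(chosen, nrow = nT, ncol = nReplicates)
    G <- nrow(cohort@geneParams)
    exprs <- matrix(NA_real_, G, need)
    time <- numeric(need)
    repl <- integer(need)
    prov <- data.frame(time = numeric(need), replicate = integer(need),
                       individual = integer(need))
    col <- 0L
    for (r in seq_len(nReplicates)) {
      for (ti in seq_len(nT)) {
        col <- col + 1L
        exprs[, col] <- cohort@values[, ti, slot[ti, r]]
        time[col] <- tp[ti]
        repl[col] <- r
        prov[col, ] <- list(tp[ti], r, slot[ti, r])
      }
    }
    rownames(exprs) <- rownames(cohort@geneParams)
    gp <- cohort@geneParams
    truth <- data.frame(rhythmic = gp$class == "rhythmic",
                        period = gp$period, phase = gp$phase,
                        waveform = gp$waveform)
    RhythmExperiment(exprs, time = time, replicate = repl, truth = truth,
                     provenance = prov)
  })
}

#' Single-replicate view of one simulated individual
#'
#' Wraps one individual's gene x timepoint matrix as a
#' [RhythmExperiment-class], used when original simulations are analysed
#' on the same consensus axis as resampled datasets.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param i individual index.
#' @return A single-replicate [RhythmExperiment-class].
#' @export
individualExperiment <- function(cohort, i) {
  stopifnot(is(cohort, "SimulatedCohort"))
  gp <- cohort@geneParams
  RhythmExperiment(individualMatrix(cohort, i),
                   time = timepoints(cohort),
                   replicate = rep(1L, length(timepoints(cohort))),
                   truth = data.frame(rhythmic = gp$class == "rhythmic",
                                      period = gp$period, phase = gp$phase,
                                      waveform = gp$waveform))
}
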