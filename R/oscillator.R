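#' Default limit-cycle oscillator for ODE-based simulations
#'
#' A three-variable Goodwin-type negative-feedback oscillator (Hill
#' repression of the first species by the third, first-order decay of all
#' species) used as the source of non-sinusoidal periodic waveforms for
#' [simulateODE()]. With equal degradation rates \eqn{r} the Hopf angular
#' frequency is approximately \eqn{r\sqrt3}; the default
#' `degradation = 0.163` / h (with production scaled so the repressor's
#' steady state sits above the oscillation threshold) places the
#' limit-cycle period at 24.0 h. A steep Hill exponent (10) guarantees
#' sustained oscillations and gives the spiky, asymmetric waveforms
#' typical of transcriptional feedback loops.
#'
#' Any oscillator with the same structure (a list with elements `rhs`
#' (a deSolve-style right-hand side), `parms`, `y0` and `species`) can be
#' passed to [simulateODE()] in place of this default, e.g. a full
#' mammalian clock model.
#'
#' @param production production rate of the first species (1/h).
#' @param degradation common first-order decay rate (1/h).
#' @param hill Hill exponent of the repression term.
#' @return a list with elements `rhs`, `parms`, `y0`, `species`, `name`.
#' @examples
#' osc <- goodwinOscillator()
#' cyc <- oscillatorCycle(osc)
#' round(cyc$period, 1)
#' @export
goodwinOscillator <- function(production = 14.344, degradation = 0.163,
                              hill = 10) {
  rhs <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      dX <- a / (1 + Z^h) - r * X
      dY <- r * X - r * Y
      dZ <- r * Y - r * Z
      list(c(dX, dY, dZ))
    })
  }
  list(rhs = rhs,
       parms = c(a = production, r = degradation, h = hill),
       y0 = c(X = 1, Y = 0.5, Z = 0.5),
       species = c("X", "Y", "Z"),
       name = "goodwin3")
}

#' Extract one full limit cycle from an oscillator
#'
#' Integrates the oscillator well past its transient, locates successive
#' maxima of the first species to estimate the limit-cycle period, and
#' returns one full cycle of every species as interpolating functions of
#' cycle phase (hours in `[0, period)`).
#'
#' @param oscillator an oscillator description as returned by
#'   [goodwinOscillator()].
#' @param tEnd total integration time (hours); the first two thirds are
#'   discarded as transient.
#' @param dt output resolution of the integration (hours).
#' @return a list with elements `period` (hours), `species` (names) and
#'   `cycle` (a function `(species, phase)` returning values on the cycle).
#' @export
oscillatorCycle <- function(oscillator, tEnd = 1200, dt = 0.05) {
  tt <- seq(0, tEnd, by = dt)
  out <- deSolve::ode(y = oscillator$y0, times = tt, func = oscillator$rhs,
                      parms = oscillator$parms)
  keep <- out[, 1] >= (2 / 3) * tEnd
  tm <- out[keep, 1]
  Y <- out[keep, -1, drop = FALSE]
  v <- Y[, 1]
  n <- length(v)
  if (diff(range(v)) < 1e-3 * max(abs(mean(v)), 1))
    stop("oscillator failed to reach a periodic orbit: the trajectory ",
         "has decayed to a fixed point (oscillation range ",
         signif(diff(range(v)), 2), ")")
  pk <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (length(pk) < 3L)
    stop("oscillator failed to reach a periodic orbit within the ",
         "integration budget (", length(pk), " peaks found); increase ",
         "'tEnd' or check the model")
  pkt <- tm[pk]
  period <- mean(diff(pkt))
  if (sd(diff(pkt)) > 0.02 * period)
    stop("oscillator peak spacing has not settled (cv = ",
         signif(sd(diff(pkt)) / period, 2), "); not a stable limit cycle")
  t1 <- pkt[length(pkt)] - period
  sel <- tm >= t1 - dt & tm <= t1 + period + dt
  funs <- lapply(seq_len(ncol(Y)), function(j)
    stats::approxfun(tm[sel] - t1, Y[sel, j], rule = 2))
  names(funs) <- oscillator$species
  cycle <- function(species, phase)
    funs[[species]](phase %% period)
  list(period = period, species = oscillator$species, cycle = cycle)
}
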