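## Time-course simulation of mRNA and a diluted reporter protein.
##
## Within each schedule phase the inputs are constant and the system
##   dm/dt = betaM (1 + wR/alphaR + wD/alphaD)/(1 + wR + wD) + beta - deltaM m
##   df/dt = kTl m - mu f
## is integrated with lsoda at tight tolerances.  The guide pools track their
## driving promoter activities instantaneously (quasi-steady sgRNA pool), so
## occupancy weights are wR = KR * xR and wD = KD * xD at every instant; the
## slow dCas9 off-rate and replication-resetting kinetics are deliberately not
## modelled, matching the equilibrium-occupancy steady-state model.

#' Simulate a repression/derepression time course
#'
#' Integrates the mRNA balance under competitive occupancy plus a reporter
#' observable with lumped translation/maturation rate and first-order dilution
#' at the growth rate.  Inputs change instantaneously at schedule events
#' (washout is an event that drops an input to zero); the state (m, f) is
#' continuous across events, since per-cell fluorescence is invariant to
#' dilution at constant growth.
#'
#' @param schedule an \linkS4class{InductionSchedule}
#' @param params a \linkS4class{DynamicsParams}
#' @param dt output sampling interval (min)
#' @param init optional initial state \code{c(m, f)}; the default starts at
#'   the steady state of the first phase's inputs
#' @param rtol,atol integration tolerances passed to lsoda
#' @return a \linkS4class{Trajectory}; \code{phase} holds the 1-based index of
#'   the schedule event governing each sample
#' @examples
#' kin <- KineticParams(betaM = 10, beta = 0.1, deltaM = 0.2, KR = 0.043,
#'                      KD = 0.063, alphaR = 120, alphaD = 1)
#' sch <- InductionSchedule(c(0, 360), xR = c(5000, 0), xD = c(0, 5000),
#'                          duration = 480)
#' traj <- simulateCircuit(sch, DynamicsParams(kin),
#'                         init = c(0, 0), dt = 30)
#' @importFrom deSolve lsoda
#' @export
simulateCircuit <- function(schedule, params, dt = 1, init = NULL,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(is(schedule, "InductionSchedule"), is(params, "DynamicsParams"))
  kin <- params@kin
  ev <- schedule@events
  bounds <- c(ev$time, schedule@duration)

  if (is.null(init)) {
    m0 <- mrnaSteadyState(ev$xR[1], ev$xD[1], kin)
    init <- c(m0, params@kTl * m0 / params@mu)
  }
  if (any(init < 0)) stop("initial state must be non-negative")

  deriv <- function(t, state, parms) {
    prod <- mrnaProductionRate(parms$xR, parms$xD, kin)
    list(c(prod - kin@deltaM * state[1],
           params@kTl * state[1] - params@mu * state[2]))
  }

  tAll <- numeric(); mAll <- numeric(); fAll <- numeric(); phAll <- integer()
  state <- init
  for (i in seq_len(nrow(ev))) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    times <- unique(c(seq(t0, t1, by = dt), t1))
    sol <- deSolve::lsoda(y = state, times = times, func = deriv,
                          parms = list(xR = ev$xR[i], xD = ev$xD[i]),
                          rtol = rtol, atol = atol)
    keep <- if (i == 1L) seq_len(nrow(sol)) else -1L  # drop duplicated joint
    tAll <- c(tAll, sol[keep, 1])
    mAll <- c(mAll, sol[keep, 2])
    fAll <- c(fAll, sol[keep, 3])
    phAll <- c(phAll, rep.int(i, length(sol[keep, 1])))
    state <- c(sol[nrow(sol), 2], sol[nrow(sol), 3])
  }
  new("Trajectory", time = tAll, mrna = pmax(mAll, 0), fluor = pmax(fAll, 0),
      phase = phAll)
}

#' Fold change of the reporter between two trajectory times
#'
#' \code{f(tEnd)/f(tStart)}, with linear interpolation between samples.  A
#' value above 1 quantifies derepression over the window.
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param tStart,tEnd times (min) within the trajectory, tStart < tEnd
#' @return the fold change (>= 0)
#' @export
foldDerepressionAt <- function(trajectory, tStart, tEnd) {
  stopifnot(is(trajectory, "Trajectory"))
  tt <- trajectory@time
  if (tStart >= tEnd) stop("tStart must precede tEnd")
  if (tStart < min(tt) || tEnd > max(tt))
    stop("times must lie within the trajectory")
  f0 <- stats::approx(tt, trajectory@fluor, xout = tStart)$y
  f1 <- stats::approx(tt, trajectory@fluor, xout = tEnd)$y
  if (f0 == 0) stop("reporter level is zero at tStart")
  f1 / f0
}
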