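## Seed-deterministic synthetic data generators.
##
## No experimental fluorescence datasets accompany the modelled system, so
## every dataset the pipeline consumes is generated here with known ground
## truth.  Observation noise is multiplicative lognormal on the replicate
## level, emulating the geometric-mean summaries of flow-cytometry
## distributions; defaults (geometric SD 1.2, 3 replicates) are synthetic
## conventions, not measured values.

#' Observation noise model
#'
#' @slot kind "none" or "lognormal"
#' @slot geometricSd multiplicative spread (> 1 for lognormal; a replicate is
#'   the model value times exp(N(0, ln(geometricSd))))
#' @slot nReps replicates per condition
#' @slot seed RNG seed used by the generators
#' @export
setClass("NoiseModel",
  representation(kind = "character", geometricSd = "numeric",
                 nReps = "integer", seed = "integer"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("none", "lognormal"))
    msg <- c(msg, "kind must be 'none' or 'lognormal'")
  if (object@kind == "lognormal" && object@geometricSd <= 1)
    msg <- c(msg, "geometricSd must be > 1 for lognormal noise")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a noise model
#'
#' @param kind "none" (outputs equal model predictions exactly) or
#'   "lognormal"
#' @param geometricSd multiplicative geometric standard deviation
#' @param nReps replicates per condition
#' @param seed RNG seed (generators are bit-reproducible for a fixed seed)
#' @return a \linkS4class{NoiseModel}
#' @export
noiseModel <- function(kind = c("none", "lognormal"), geometricSd = 1.2,
                       nReps = 3L, seed = 1729L) {
  kind <- match.arg(kind)
  new("NoiseModel", kind = kind, geometricSd = as.numeric(geometricSd),
      nReps = as.integer(nReps), seed = as.integer(seed))
}

## run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.drawReps <- function(mu, noise) {
  # one condition: nReps multiplicative lognormal draws around the model value
  if (noise@kind == "none") rep(mu, noise@nReps)
  else mu * exp(stats::rnorm(noise@nReps, 0, log(noise@geometricSd)))
}

#' Generate a synthetic single-guide induction curve
#'
#' Per input level, \code{nReps} replicate draws around the single-guide
#' response; the curve stores the replicate means, standard deviations and
#' the raw draws.
#'
#' @param params generating \linkS4class{SteadyStateParams}
#' @param xLevels promoter-activity levels (au)
#' @param noise a \linkS4class{NoiseModel}
#' @return an \linkS4class{InductionCurve}
#' @examples
#' truth <- SteadyStateParams(16, 6800, 0.043, 120)
#' cur <- genInductionCurve(truth, defaultActivityLevels(),
#'                          noiseModel("lognormal", seed = 7L))
#' @export
genInductionCurve <- function(params, xLevels, noise = noiseModel("none")) {
  stopifnot(is(params, "SteadyStateParams"), is(noise, "NoiseModel"))
  mu <- responseSingle(xLevels, params)
  reps <- .withSeed(noise@seed,
    t(vapply(mu, .drawReps, numeric(noise@nReps), noise = noise)))
  if (noise@nReps == 1L) reps <- matrix(reps, ncol = 1L)
  InductionCurve(x = xLevels, yMean = rowMeans(reps),
                 ySd = apply(reps, 1, stats::sd), nReps = noise@nReps,
                 reps = reps)
}

#' Generate a synthetic dual-guide response grid
#'
#' Cell-wise replicate draws around the dual-guide response; conditions are
#' drawn column by column (xD outer, xR inner), so a single-column grid with
#' \code{xDLevels = 0} consumes the same random stream as
#' \code{\link{genInductionCurve}} at the same seed.
#'
#' @param params generating \linkS4class{SteadyStateParams} (dual)
#' @param xRLevels,xDLevels input levels (au)
#' @param noise a \linkS4class{NoiseModel}
#' @return a \linkS4class{ResponseGrid}
#' @export
genResponseGrid <- function(params, xRLevels, xDLevels,
                            noise = noiseModel("none")) {
  stopifnot(is(params, "SteadyStateParams"), is(noise, "NoiseModel"))
  xRLevels <- sort(as.numeric(xRLevels))
  xDLevels <- sort(as.numeric(xDLevels))
  nR <- length(xRLevels); nD <- length(xDLevels)
  mu <- outer(xRLevels, xDLevels,
              function(a, b) responseDual(a, b, params))
  yM <- matrix(0, nR, nD); yS <- matrix(0, nR, nD)
  .withSeed(noise@seed, for (j in seq_len(nD)) for (i in seq_len(nR)) {
    d <- .drawReps(mu[i, j], noise)
    yM[i, j] <- mean(d)
    yS[i, j] <- stats::sd(d)
  })
  ResponseGrid(xRLevels, xDLevels, yM, yS)
}

#' Generate a synthetic repression/derepression time course
#'
#' Simulates the circuit under the schedule, then applies multiplicative
#' lognormal observation noise to the reporter at the sampled times.
#'
#' @param schedule an \linkS4class{InductionSchedule}
#' @param params a \linkS4class{DynamicsParams}
#' @param samplingInterval observation spacing (min)
#' @param noise a \linkS4class{NoiseModel}
#' @param init optional initial state passed to
#'   \code{\link{simulateCircuit}}
#' @return a list with \code{trajectory} (noise-free
#'   \linkS4class{Trajectory}) and \code{observations} (data.frame with
#'   columns time_min, fluorescence_au, sd_au, phase)
#' @export
genTimecourse <- function(schedule, params, samplingInterval = 30,
                          noise = noiseModel("none"), init = NULL) {
  traj <- simulateCircuit(schedule, params, dt = samplingInterval,
                          init = init)
  f <- traj@fluor
  reps <- .withSeed(noise@seed,
    t(vapply(f, .drawReps, numeric(noise@nReps), noise = noise)))
  if (noise@nReps == 1L) reps <- matrix(reps, ncol = 1L)
  list(trajectory = traj,
       observations = data.frame(time_min = traj@time,
                                 fluorescence_au = rowMeans(reps),
                                 sd_au = apply(reps, 1, stats::sd),
                                 phase = traj@phase))
}

#' Sample lognormal cytometry-like events
#'
#' @param geometricMean geometric mean of the event distribution (au)
#' @param geometricSd geometric standard deviation (>= 1)
#' @param n number of events (>= 1)
#' @param seed RNG seed
#' @return numeric vector of positive event intensities
#' @export
sampleEvents <- function(geometricMean, geometricSd, n, seed = 1729L) {
  if (n < 1) stop("n must be >= 1")
  if (geometricSd < 1) stop("geometricSd must be >= 1")
  if (geometricMean <= 0) stop("geometricMean must be > 0")
  .withSeed(seed,
    exp(stats::rnorm(n, log(geometricMean), log(geometricSd))))
}

#' Geometric mean of event intensities
#'
#' exp(mean(ln(events))); the summary statistic applied to cytometry
#' distributions.
#'
#' @param events positive event intensities
#' @return the geometric mean (au)
#' @export
geometricMeanOf <- function(events) {
  if (any(events <= 0)) stop("events must be positive")
  exp(mean(log(events)))
}

## ---------------------------------------------------------------------------
## Reference parameter sets and standard level layouts
## ---------------------------------------------------------------------------

#' Published example parameter sets for repression/derepression circuits
#'
#' Representative fitted parameters for E. coli dCas9
#' repression/derepression circuits: two promoter-targeting repressor guides
#' ("promoter_single" targets the -35 core, "promoter_single_alt" the -10
#' core), the promoter circuit with its derepressor added
#' ("promoter_dual"), and the elongation-blocking circuit
#' ("elongation_single"/"elongation_dual").  These serve as ground truth for
#' the synthetic generators and parameter-recovery checks.
#'
#' @param name which parameter set
#' @return a \linkS4class{SteadyStateParams}
#' @export
exampleCircuitParams <- function(name = c("promoter_single",
                                          "promoter_single_alt",
                                          "promoter_dual",
                                          "elongation_single",
                                          "elongation_dual")) {
  name <- match.arg(name)
  switch(name,
    promoter_single = SteadyStateParams(16, 6800, 0.043, 120),
    promoter_single_alt = SteadyStateParams(1.2, 7700, 0.10, 150),
    promoter_dual = SteadyStateParams(16, 6800, 0.043, 120,
                                      kappaD = 0.063, alphaD = 1.0),
    elongation_single = SteadyStateParams(37, 4200, 0.019, 27),
    elongation_dual = SteadyStateParams(37, 4200, 0.019, 27,
                                        kappaD = 0.0077, alphaD = 1.0))
}

#' Standard promoter-activity level layouts
#'
#' \code{defaultActivityLevels()} is the 12-level single-titration layout
#' (zero plus 11 log-spaced levels from \code{from} to \code{to} au);
#' \code{gridActivityLevels()} gives the 7 x 11 dual-grid layout (zero plus 6
#' log-spaced repressor levels and zero plus 10 log-spaced derepressor
#' levels).
#'
#' @param n number of positive levels
#' @param from,to positive level range (au)
#' @return numeric vector of levels for \code{defaultActivityLevels}; a list
#'   with \code{xR} and \code{xD} for \code{gridActivityLevels}
#' @export
defaultActivityLevels <- function(n = 11, from = 1, to = 8000) {
  c(0, 10^seq(log10(from), log10(to), length.out = n))
}

#' @rdname defaultActivityLevels
#' @export
gridActivityLevels <- function(from = 1, to = 8000) {
  list(xR = c(0, 10^seq(log10(from), log10(to), length.out = 6)),
       xD = c(0, 10^seq(log10(from), log10(to), length.out = 10)))
}
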