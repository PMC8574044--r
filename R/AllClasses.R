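#' @import methods
NULL

## ---------------------------------------------------------------------------
## Parameter containers
## ---------------------------------------------------------------------------

#' Observable-scale steady-state model parameters
#'
#' Parameters of the fluorescence-scale competitive-occupancy response.  For a
#' single repressing guide the output at promoter-activity input \eqn{x_R} is
#' \deqn{y = (y_{max}-y_{min})\frac{1 + \alpha_R^{-1}\kappa_R x_R}
#'                                 {1 + \kappa_R x_R} + y_{min},}
#' and with a second, derepressing guide driven at activity \eqn{x_D}
#' \deqn{y = (y_{max}-y_{min})\frac{1 + \alpha_R^{-1}\kappa_R x_R +
#'        \alpha_D^{-1}\kappa_D x_D}{1 + \kappa_R x_R + \kappa_D x_D} + y_{min}.}
#' \eqn{\kappa} rescales the association constant into reciprocal
#' promoter-activity units (au\eqn{^{-1}}) and \eqn{\alpha} is the fold
#' reduction in production when the locus is saturated by the corresponding
#' dCas9:sgRNA species (\eqn{\alpha = 1} means a transcriptionally neutral
#' binder).  The leaky-transcription floor is absorbed into \code{yMin}, so the
#' response at zero inputs is exactly \code{yMax} and the fully repressed floor
#' is \code{yMin}-anchored.
#'
#' \code{kappaD}/\code{alphaD} are \code{NA} for a single-guide parameter set.
#'
#' @slot yMin minimum measured output (au RFP fluorescence, >= 0)
#' @slot yMax maximum measured output (au, > yMin)
#' @slot kappaR rescaled association constant of the repressing guide (au^-1)
#' @slot kappaD rescaled association constant of the derepressing guide
#'   (au^-1), or NA
#' @slot alphaR fold-repression at saturation by the repressing guide (> 0)
#' @slot alphaD fold-repression at saturation by the derepressing guide, or NA
#' @export
setClass("SteadyStateParams",
  representation(
    yMin = "numeric", yMax = "numeric",
    kappaR = "numeric", kappaD = "numeric",
    alphaR = "numeric", alphaD = "numeric"
  ),
  prototype(kappaD = NA_real_, alphaD = NA_real_)
)

setValidity("SteadyStateParams", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.numeric(x)
  if (!all(vapply(list(object@yMin, object@yMax, object@kappaR,
                       object@kappaD, object@alphaR, object@alphaD),
                  num1, logical(1))))
    return("all slots must be numeric scalars")
  if (is.na(object@yMin) || object@yMin < 0) msg <- c(msg, "yMin must be >= 0")
  if (is.na(object@yMax) || object@yMax <= object@yMin)
    msg <- c(msg, "yMax must exceed yMin")
  if (is.na(object@kappaR) || object@kappaR <= 0)
    msg <- c(msg, "kappaR must be > 0")
  if (is.na(object@alphaR) || object@alphaR <= 0)
    msg <- c(msg, "alphaR must be > 0")
  if (!is.na(object@kappaD) && object@kappaD <= 0)
    msg <- c(msg, "kappaD must be > 0 when present")
  if (!is.na(object@alphaD) && object@alphaD <= 0)
    msg <- c(msg, "alphaD must be > 0 when present")
  if (xor(is.na(object@kappaD), is.na(object@alphaD)))
    msg <- c(msg, "kappaD and alphaD must be supplied together")
  if (length(msg)) msg else TRUE
})

#' Construct observable-scale model parameters
#'
#' @param yMin,yMax fluorescence floor and ceiling (au)
#' @param kappaR,alphaR repressing-guide association constant (au^-1) and
#'   saturation fold-repression
#' @param kappaD,alphaD derepressing-guide counterparts; leave \code{NA} for a
#'   single-guide model
#' @return a \linkS4class{SteadyStateParams} object
#' @examples
#' p <- SteadyStateParams(yMin = 16, yMax = 6800, kappaR = 0.043, alphaR = 120)
#' responseSingle(0, p)  # == yMax
#' @export
SteadyStateParams <- function(yMin, yMax, kappaR, alphaR,
                              kappaD = NA_real_, alphaD = NA_real_) {
  new("SteadyStateParams",
      yMin = as.numeric(yMin), yMax = as.numeric(yMax),
      kappaR = as.numeric(kappaR), kappaD = as.numeric(kappaD),
      alphaR = as.numeric(alphaR), alphaD = as.numeric(alphaD))
}

#' Mechanistic (mRNA-scale) kinetic parameters
#'
#' Rates of the mRNA balance
#' \deqn{dm/dt = \beta_m\frac{1+\alpha_R^{-1}K_R S_R+\alpha_D^{-1}K_D S_D}
#'                           {1+K_R S_R+K_D S_D} + \beta - \delta_m m,}
#' where \eqn{\beta_m/\alpha_R} and \eqn{\beta_m/\alpha_D} are the maximum
#' transcription rates when either dCas9:sgRNA species saturates the locus and
#' \eqn{\beta} is leaky transcription.
#'
#' @slot betaM maximum transcription rate (mRNA/time, > 0)
#' @slot beta leaky transcription rate (mRNA/time, >= 0)
#' @slot deltaM mRNA degradation rate (1/time, > 0)
#' @slot KR,KD association constants of the repressing/derepressing dCas9
#'   complexes with the locus (reciprocal concentration)
#' @slot alphaR,alphaD saturation fold-repression of each species (> 0)
#' @export
setClass("KineticParams",
  representation(
    betaM = "numeric", beta = "numeric", deltaM = "numeric",
    KR = "numeric", KD = "numeric",
    alphaR = "numeric", alphaD = "numeric"
  )
)

setValidity("KineticParams", function(object) {
  msg <- character()
  if (object@betaM <= 0) msg <- c(msg, "betaM must be > 0")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (object@deltaM <= 0) msg <- c(msg, "deltaM must be > 0")
  if (object@KR <= 0 || object@KD <= 0) msg <- c(msg, "KR and KD must be > 0")
  if (object@alphaR <= 0 || object@alphaD <= 0)
    msg <- c(msg, "alphaR and alphaD must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct kinetic parameters
#'
#' @param betaM,beta,deltaM transcription, leak and degradation rates
#' @param KR,KD association constants
#' @param alphaR,alphaD saturation fold-repressions
#' @return a \linkS4class{KineticParams} object
#' @export
KineticParams <- function(betaM, beta, deltaM, KR, KD = KR,
                          alphaR, alphaD = 1) {
  new("KineticParams", betaM = as.numeric(betaM), beta = as.numeric(beta),
      deltaM = as.numeric(deltaM), KR = as.numeric(KR), KD = as.numeric(KD),
      alphaR = as.numeric(alphaR), alphaD = as.numeric(alphaD))
}

## ---------------------------------------------------------------------------
## Dose-response data containers
## ---------------------------------------------------------------------------

#' One-dimensional induction curve
#'
#' Promoter-activity inputs against geometric-mean fluorescence outputs, as
#' produced by titrating a single guide-driving inducible promoter.  Points are
#' stored sorted by increasing input.  Replicate-level draws are retained (when
#' available) in \code{reps}, one row per input level.
#'
#' @slot x promoter-activity inputs (au, >= 0), non-decreasing
#' @slot yMean per-level mean fluorescence (au, > 0)
#' @slot ySd per-level replicate standard deviation (au), or zero-length
#' @slot nReps replicate count per level
#' @slot reps replicate draws (levels x replicates), or 0x0
#' @export
setClass("InductionCurve",
  representation(x = "numeric", yMean = "numeric", ySd = "numeric",
                 nReps = "integer", reps = "matrix"),
  prototype(ySd = numeric(), nReps = 1L, reps = matrix(numeric(), 0, 0))
)

setValidity("InductionCurve", function(object) {
  msg <- character()
  if (length(object@x) != length(object@yMean))
    msg <- c(msg, "x and yMean must have equal length")
  if (any(object@x < 0)) msg <- c(msg, "x must be >= 0")
  if (is.unsorted(object@x)) msg <- c(msg, "x must be non-decreasing")
  if (any(object@yMean <= 0)) msg <- c(msg, "yMean must be > 0")
  if (length(object@ySd) && length(object@ySd) != length(object@x))
    msg <- c(msg, "ySd length must match x")
  if (nrow(object@reps) && nrow(object@reps) != length(object@x))
    msg <- c(msg, "reps must have one row per level")
  if (length(msg)) msg else TRUE
})

#' Construct an induction curve
#'
#' Points are sorted by increasing input on ingestion.
#'
#' @param x promoter-activity inputs (au)
#' @param yMean mean fluorescence per input (au)
#' @param ySd optional replicate standard deviations
#' @param nReps replicates per point
#' @param reps optional matrix of replicate draws (levels x replicates)
#' @return an \linkS4class{InductionCurve}
#' @export
InductionCurve <- function(x, yMean, ySd = numeric(), nReps = 1L,
                           reps = matrix(numeric(), 0, 0)) {
  ord <- order(x)
  x <- as.numeric(x)[ord]
  yMean <- as.numeric(yMean)[ord]
  if (length(ySd)) ySd <- as.numeric(ySd)[ord]
  if (nrow(reps)) reps <- reps[ord, , drop = FALSE]
  new("InductionCurve", x = x, yMean = yMean, ySd = ySd,
      nReps = as.integer(nReps), reps = reps)
}

#' Two-dimensional dual-induction response grid
#'
#' Mean fluorescence for every combination of repressing-guide and
#' derepressing-guide promoter activities.  Rows index \code{xRLevels},
#' columns index \code{xDLevels}.
#'
#' @slot xRLevels repressing-guide promoter activities (au)
#' @slot xDLevels derepressing-guide promoter activities (au)
#' @slot y mean fluorescence matrix (length(xRLevels) x length(xDLevels))
#' @slot ySd optional matching matrix of replicate standard deviations
#' @export
setClass("ResponseGrid",
  representation(xRLevels = "numeric", xDLevels = "numeric",
                 y = "matrix", ySd = "matrix"),
  prototype(ySd = matrix(numeric(), 0, 0))
)

setValidity("ResponseGrid", function(object) {
  msg <- character()
  if (nrow(object@y) != length(object@xRLevels) ||
      ncol(object@y) != length(object@xDLevels))
    msg <- c(msg, "y must be length(xRLevels) x length(xDLevels)")
  if (any(object@xRLevels < 0) || any(object@xDLevels < 0))
    msg <- c(msg, "levels must be >= 0")
  if (nrow(object@ySd) && !identical(dim(object@ySd), dim(object@y)))
    msg <- c(msg, "ySd dimensions must match y")
  if (length(msg)) msg else TRUE
})

#' Construct a response grid
#'
#' @param xRLevels,xDLevels input activity levels (au)
#' @param y fluorescence matrix, rows = xRLevels, cols = xDLevels
#' @param ySd optional matching SD matrix
#' @return a \linkS4class{ResponseGrid}
#' @export
ResponseGrid <- function(xRLevels, xDLevels, y,
                         ySd = matrix(numeric(), 0, 0)) {
  new("ResponseGrid", xRLevels = as.numeric(xRLevels),
      xDLevels = as.numeric(xDLevels), y = y, ySd = ySd)
}

#' Result of a nonlinear least-squares model fit
#'
#' @slot params fitted \linkS4class{SteadyStateParams}
#' @slot freeNames names of the parameters that were free in the fit
#' @slot rSquared coefficient of determination over the fitted points
#' @slot residuals per-point residuals (observed - predicted)
#' @slot converged optimizer convergence flag
#' @slot nIter optimizer iteration count
#' @slot unidentifiable names of parameters flagged unidentifiable (e.g. a
#'   flat curve leaves kappa and alpha unconstrained)
#' @export
setClass("FitResult",
  representation(params = "SteadyStateParams", freeNames = "character",
                 rSquared = "numeric", residuals = "numeric",
                 converged = "logical", nIter = "integer",
                 unidentifiable = "character")
)

setValidity("FitResult", function(object) {
  if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-12)
    "rSquared cannot exceed 1" else TRUE
})

#' Ratio-of-means estimate with propagated uncertainty
#'
#' Holds \eqn{\hat\alpha = A/B} and the first-order propagated standard
#' deviation \eqn{\sigma = |A/B|\sqrt{(\sigma_A/A)^2 + (\sigma_B/B)^2}}.
#'
#' @slot alpha the ratio estimate (> 0)
#' @slot sigma propagated standard deviation (>= 0)
#' @export
setClass("AlphaEstimate",
  representation(alpha = "numeric", sigma = "numeric"))

setValidity("AlphaEstimate", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Transfer functions
## ---------------------------------------------------------------------------

#' Hill-form inducer-to-promoter-activity transfer function
#'
#' Converts an inducer concentration (uM) to the activity of the corresponding
#' inducible promoter in fluorescence-calibrated units (au):
#' \deqn{a(c) = basal + (maximal - basal)\frac{c^n}{h^n + c^n}.}
#' Strictly increasing on its domain, with \code{forward(0) = basal} and the
#' saturating asymptote \code{maximal}.
#'
#' @slot basal activity at zero inducer (au, >= 0)
#' @slot maximal activity at saturation (au, > basal)
#' @slot halfMax inducer concentration at half-maximal response (uM, > 0)
#' @slot hillN cooperativity (> 0)
#' @slot inducerName label, e.g. "IPTG"
#' @export
setClass("HillTransfer",
  representation(basal = "numeric", maximal = "numeric", halfMax = "numeric",
                 hillN = "numeric", inducerName = "character"),
  prototype(inducerName = "")
)

setValidity("HillTransfer", function(object) {
  msg <- character()
  if (object@basal < 0) msg <- c(msg, "basal must be >= 0")
  if (object@maximal <= object@basal) msg <- c(msg, "maximal must exceed basal")
  if (object@halfMax <= 0) msg <- c(msg, "halfMax must be > 0")
  if (object@hillN <= 0) msg <- c(msg, "hillN must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Hill transfer function
#'
#' @param basal,maximal activity range (au)
#' @param halfMax half-maximal inducer concentration (uM)
#' @param hillN Hill coefficient
#' @param inducerName inducer label
#' @return a \linkS4class{HillTransfer}
#' @export
HillTransfer <- function(basal, maximal, halfMax, hillN = 1,
                         inducerName = "") {
  new("HillTransfer", basal = as.numeric(basal), maximal = as.numeric(maximal),
      halfMax = as.numeric(halfMax), hillN = as.numeric(hillN),
      inducerName = inducerName)
}

## ---------------------------------------------------------------------------
## Guide geometry
## ---------------------------------------------------------------------------

#' A guide-RNA target site on a reference sequence
#'
#' Coordinates are 1-based inclusive on the top strand of the reference.  The
#' 20-nt protospacer is immediately 5' of the 3-nt NGG PAM on the strand that
#' carries them (\code{strand}); the sgRNA spacer sequence equals the
#' protospacer sequence and base-pairs with the opposite strand.
#'
#' @slot spacer 20-nt spacer sequence, 5'->3' as in the sgRNA
#' @slot strand "top" or "bottom": the strand carrying protospacer and PAM
#' @slot protoStart,protoEnd protospacer top-strand coordinates
#' @slot pamStart,pamEnd PAM top-strand coordinates
#' @export
setClass("GuideSite",
  representation(spacer = "character", strand = "character",
                 protoStart = "integer", protoEnd = "integer",
                 pamStart = "integer", pamEnd = "integer")
)

setValidity("GuideSite", function(object) {
  msg <- character()
  if (!object@strand %in% c("top", "bottom"))
    msg <- c(msg, "strand must be 'top' or 'bottom'")
  if (nchar(object@spacer) != 20L) msg <- c(msg, "spacer must be 20 nt")
  if (object@protoEnd - object@protoStart != 19L)
    msg <- c(msg, "protospacer must span 20 bp")
  if (object@pamEnd - object@pamStart != 2L) msg <- c(msg, "PAM must span 3 bp")
  adjacent <- if (object@strand == "top")
    object@pamStart == object@protoEnd + 1L
  else
    object@pamEnd == object@protoStart - 1L
  if (!length(msg) && !adjacent)
    msg <- c(msg, "PAM must be immediately 3' of the protospacer on its strand")
  if (length(msg)) msg else TRUE
})

#' Verdict for a repressor/derepressor guide pair
#'
#' Encodes the steric-competition design rules: two non-overlapping sites
#' compete for dCas9 occupancy when the protein footprints overlap, which
#' requires the PAMs to face each other (dCas9 overhangs ~9 bp beyond the
#' PAM-proximal edge of its target but only ~1 bp beyond the PAM-distal edge).
#'
#' @slot gapBp gap (bp) between the nearest site edges (see
#'   \code{\link{classifyPair}} for the measurement convention)
#' @slot pamsFacing TRUE when both PAMs lie between the two protospacers
#' @slot competitive "validated", "marginal" or "independent"
#' @slot sgdRepressionRisk "none", "partial" or "high": the risk that the
#'   derepressing guide represses on its own
#' @slot context "promoter" or "elongation"
#' @export
setClass("PairClassification",
  representation(gapBp = "integer", pamsFacing = "logical",
                 competitive = "character", sgdRepressionRisk = "character",
                 context = "character")
)

setValidity("PairClassification", function(object) {
  msg <- character()
  if (!object@competitive %in% c("validated", "marginal", "independent"))
    msg <- c(msg, "invalid competitive verdict")
  if (!object@sgdRepressionRisk %in% c("none", "partial", "high"))
    msg <- c(msg, "invalid risk level")
  if (!object@context %in% c("promoter", "elongation"))
    msg <- c(msg, "invalid context")
  if (object@competitive == "validated" &&
      !(object@pamsFacing && object@gapBp <= 14L))
    msg <- c(msg, "validated requires facing PAMs and gap <= 14 bp")
  if (object@competitive == "marginal" &&
      !(object@pamsFacing && object@gapBp >= 15L && object@gapBp <= 18L))
    msg <- c(msg, "marginal requires facing PAMs and gap in 15..18 bp")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Dynamics
## ---------------------------------------------------------------------------

#' Piecewise-constant induction schedule
#'
#' Events set the promoter activities driving the repressing and derepressing
#' guides from their time onward; the first event must be at time 0.  A
#' washout is represented as an event that changes the inputs.
#'
#' @slot events data.frame with columns time (min), xR (au), xD (au)
#' @slot duration total simulated time (min)
#' @export
setClass("InductionSchedule",
  representation(events = "data.frame", duration = "numeric"))

setValidity("InductionSchedule", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("time", "xR", "xD") %in% names(ev)))
    msg <- c(msg, "events needs columns time, xR, xD")
  else {
    if (nrow(ev) < 1L || ev$time[1] != 0)
      msg <- c(msg, "first event must be at time 0")
    if (any(diff(ev$time) <= 0)) msg <- c(msg, "event times must increase")
    if (any(ev$xR < 0) || any(ev$xD < 0)) msg <- c(msg, "inputs must be >= 0")
    if (object@duration <= max(ev$time))
      msg <- c(msg, "duration must exceed the last event time")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an induction schedule
#'
#' @param times event times (min), starting at 0, strictly increasing
#' @param xR,xD repressing/derepressing promoter activities from each event
#'   onward (au); recycled to the number of events
#' @param duration total simulated time (min)
#' @return an \linkS4class{InductionSchedule}
#' @examples
#' # repress for 360 min, then wash out the repressor and induce derepression
#' InductionSchedule(times = c(0, 360), xR = c(5000, 0), xD = c(0, 5000),
#'                   duration = 480)
#' @export
InductionSchedule <- function(times, xR, xD, duration) {
  ev <- data.frame(time = as.numeric(times),
                   xR = rep_len(as.numeric(xR), length(times)),
                   xD = rep_len(as.numeric(xD), length(times)))
  new("InductionSchedule", events = ev, duration = as.numeric(duration))
}

#' Dynamics parameters: kinetics plus reporter observation
#'
#' The reporter fluorescence proxy f obeys \eqn{df/dt = k_{tl} m - \mu f},
#' a lumped translation/maturation rate and first-order dilution at the
#' cellular growth rate (stable reporter protein, no active degradation).
#'
#' @slot kin \linkS4class{KineticParams} for the mRNA balance
#' @slot kTl lumped translation/maturation rate (au per mRNA per min)
#' @slot mu dilution rate, ln(2)/doublingTime (1/min)
#' @slot doublingTime culture doubling time (min)
#' @export
setClass("DynamicsParams",
  representation(kin = "KineticParams", kTl = "numeric", mu = "numeric",
                 doublingTime = "numeric"))

setValidity("DynamicsParams", function(object) {
  msg <- character()
  if (object@kTl <= 0) msg <- c(msg, "kTl must be > 0")
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (abs(object@mu - log(2) / object@doublingTime) > 1e-12)
    msg <- c(msg, "mu must equal ln(2)/doublingTime")
  if (length(msg)) msg else TRUE
})

#' Construct dynamics parameters
#'
#' @param kin \linkS4class{KineticParams}
#' @param kTl translation/maturation lump rate (au per mRNA per min)
#' @param doublingTime culture doubling time (min); the dilution rate is
#'   derived as ln(2)/doublingTime
#' @return a \linkS4class{DynamicsParams}
#' @export
DynamicsParams <- function(kin, kTl = 1, doublingTime = 36) {
  new("DynamicsParams", kin = kin, kTl = as.numeric(kTl),
      mu = log(2) / doublingTime, doublingTime = as.numeric(doublingTime))
}

#' Simulated time course of mRNA and reporter
#'
#' @slot time sampling times (min)
#' @slot mrna mRNA level
#' @slot fluor reporter fluorescence proxy (au)
#' @slot phase schedule phase index per sample (1-based event index)
#' @export
setClass("Trajectory",
  representation(time = "numeric", mrna = "numeric", fluor = "numeric",
                 phase = "integer"))

setValidity("Trajectory", function(object) {
  n <- length(object@time)
  msg <- character()
  if (length(object@mrna) != n || length(object@fluor) != n ||
      length(object@phase) != n)
    msg <- c(msg, "time, mrna, fluor, phase must have equal length")
  if (any(object@mrna < -1e-9) || any(object@fluor < -1e-9))
    msg <- c(msg, "mrna and fluor must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Ratiometric
## ---------------------------------------------------------------------------

#' Grid response collapsed onto the input-ratio axis
#'
#' One point per grid cell with both inputs positive; \code{ratio} is
#' \eqn{x_D/x_R}.  Cells with a zero input are excluded and counted.
#'
#' @slot ratio input ratios (dimensionless, > 0)
#' @slot y outputs (au)
#' @slot sourceCells data.frame (row, col, xR, xD) indexing the source grid
#' @slot dynamicRange max(y)/min(y) over points with ratio >= 1
#' @slot excludedCells number of grid cells dropped for a zero input
#' @export
setClass("RatioResponse",
  representation(ratio = "numeric", y = "numeric", sourceCells = "data.frame",
                 dynamicRange = "numeric", excludedCells = "integer"))

setValidity("RatioResponse", function(object) {
  msg <- character()
  if (any(object@ratio <= 0)) msg <- c(msg, "ratios must be > 0")
  if (length(object@y) != length(object@ratio))
    msg <- c(msg, "y and ratio must have equal length")
  if (length(msg)) msg else TRUE
})
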