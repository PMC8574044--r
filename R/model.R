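## Closed-form competitive-occupancy and transcription model.

#' Equilibrium occupancy of a locus competed for by two dCas9:sgRNA species
#'
#' At equilibrium the locus partitions between free (P), repressor-bound (P_R)
#' and derepressor-bound (P_D) states with statistical weights 1, K_R S_R and
#' K_D S_D.  Binding is mutually exclusive, so the fractions are the weights
#' normalized by the partition function 1 + K_R S_R + K_D S_D.
#'
#' @param sR,sD concentrations of the dCas9:sgR and dCas9:sgD complexes
#'   (arbitrary concentration units, >= 0); vectors are recycled
#' @param KR,KD association constants (reciprocal concentration units, > 0)
#' @return a data.frame with columns \code{fFree}, \code{fR}, \code{fD}
#'   (fractions summing to 1)
#' @examples
#' occupancy(sR = 1, sD = 1, KR = 1, KD = 1)  # 1/3 each
#' @export
occupancy <- function(sR, sD = 0, KR, KD = KR) {
  if (any(sR < 0) || any(sD < 0))
    stop("concentrations sR and sD must be >= 0")
  if (any(KR <= 0) || any(KD <= 0))
    stop("association constants KR and KD must be > 0")
  fFree <- 1 / (1 + KR * sR + KD * sD)
  data.frame(fFree = fFree, fR = KR * sR * fFree, fD = KD * sD * fFree)
}

#' Instantaneous mRNA production rate under competitive occupancy
#'
#' \deqn{\beta_m\frac{1+\alpha_R^{-1}K_R S_R+\alpha_D^{-1}K_D S_D}
#'                   {1+K_R S_R+K_D S_D}+\beta,}
#' equivalently \eqn{\beta_m (f_{free} + f_R/\alpha_R + f_D/\alpha_D) + \beta}:
#' the free locus produces at the maximal rate, a bound locus at the maximal
#' rate divided by that binder's fold-repression \eqn{\alpha}, plus leak.
#'
#' @param sR,sD dCas9:sgRNA complex concentrations (>= 0)
#' @param kin a \linkS4class{KineticParams}
#' @return production rate (mRNA per unit time)
#' @export
mrnaProductionRate <- function(sR, sD = 0, kin) {
  stopifnot(is(kin, "KineticParams"))
  if (any(sR < 0) || any(sD < 0)) stop("sR and sD must be >= 0")
  wR <- kin@KR * sR
  wD <- kin@KD * sD
  kin@betaM * (1 + wR / kin@alphaR + wD / kin@alphaD) / (1 + wR + wD) +
    kin@beta
}

#' Steady-state mRNA level
#'
#' Production rate divided by the mRNA degradation rate; this is the long-time
#' limit of the mRNA balance ODE at constant inputs.
#'
#' @inheritParams mrnaProductionRate
#' @return steady-state mRNA level
#' @export
mrnaSteadyState <- function(sR, sD = 0, kin) {
  stopifnot(is(kin, "KineticParams"))
  if (kin@deltaM <= 0) stop("deltaM must be > 0")
  mrnaProductionRate(sR, sD, kin) / kin@deltaM
}

## shared kernel of the observable-scale response; weights may be Inf
.responseKernel <- function(wR, wD, yMin, yMax, alphaR, alphaD) {
  out <- numeric(length(wR))
  bothInf <- is.infinite(wR) & is.infinite(wD)
  rInf <- is.infinite(wR) & !bothInf
  dInf <- is.infinite(wD) & !bothInf
  fin <- !(bothInf | rInf | dInf)
  out[bothInf] <- NaN
  out[rInf] <- (yMax - yMin) / alphaR + yMin
  out[dInf] <- (yMax - yMin) / alphaD + yMin
  out[fin] <- (yMax - yMin) *
    (1 + wR[fin] / alphaR + wD[fin] / alphaD) / (1 + wR[fin] + wD[fin]) + yMin
  out
}

#' Observable-scale single-guide response
#'
#' Fluorescence output as a function of the activity of the promoter driving
#' the repressing guide.  Zero input returns \code{yMax}; the saturating floor
#' is \eqn{(y_{max}-y_{min})/\alpha_R + y_{min}}.  The response is strictly
#' decreasing in \code{xR} when \eqn{\alpha_R > 1}.
#'
#' @param xR promoter activity driving the repressing guide (au, >= 0);
#'   \code{Inf} evaluates the saturation limit
#' @param params a \linkS4class{SteadyStateParams}
#' @return fluorescence (au), vectorized over \code{xR}
#' @examples
#' p <- SteadyStateParams(16, 6800, 0.043, 120)
#' responseSingle(c(0, Inf), p)
#' @export
responseSingle <- function(xR, params) {
  stopifnot(is(params, "SteadyStateParams"))
  if (any(xR < 0)) stop("xR must be >= 0")
  .responseKernel(params@kappaR * xR, rep(0, length(xR)),
                  params@yMin, params@yMax, params@alphaR, 1)
}

#' Observable-scale dual-guide response
#'
#' Fluorescence output under simultaneous induction of the repressing
#' (\code{xR}) and derepressing (\code{xD}) guides.  Reduces exactly to
#' \code{\link{responseSingle}} at \code{xD = 0}.  With \eqn{\alpha_D = 1}
#' the derepressor-saturated asymptote is \code{yMax}: full derepression.
#'
#' @param xR,xD promoter activities (au, >= 0); \code{Inf} evaluates the
#'   corresponding saturation limit (both infinite is indeterminate: NaN)
#' @param params a \linkS4class{SteadyStateParams} with \code{kappaD} and
#'   \code{alphaD} set (required when any \code{xD > 0})
#' @return fluorescence (au), vectorized
#' @export
responseDual <- function(xR, xD, params) {
  stopifnot(is(params, "SteadyStateParams"))
  if (any(xR < 0) || any(xD < 0)) stop("xR and xD must be >= 0")
  n <- max(length(xR), length(xD))
  xR <- rep_len(xR, n)
  xD <- rep_len(xD, n)
  if (any(xD > 0) && (is.na(params@kappaD) || is.na(params@alphaD)))
    stop("params lacks kappaD/alphaD but xD > 0 was supplied")
  kD <- if (is.na(params@kappaD)) 0 else params@kappaD
  aD <- if (is.na(params@alphaD)) 1 else params@alphaD
  .responseKernel(params@kappaR * xR, kD * xD,
                  params@yMin, params@yMax, params@alphaR, aD)
}

#' Fold change between two input states
#'
#' Ratio of the dual-guide response evaluated at two input pairs, e.g. the
#' asymptotic maximal fold-repression between the unrepressed and fully
#' repressed states.
#'
#' @param params a \linkS4class{SteadyStateParams}
#' @param from,to numeric length-2 vectors \code{c(xR, xD)}; \code{Inf}
#'   components evaluate saturation limits
#' @return \code{response(from) / response(to)} (>= 0)
#' @examples
#' p <- SteadyStateParams(16, 6800, 0.043, 120)
#' foldChange(p, from = c(0, 0), to = c(Inf, 0))  # ~93.75-fold repression
#' @export
foldChange <- function(params, from, to) {
  yFrom <- responseDual(from[1], from[2], params)
  yTo <- responseDual(to[1], to[2], params)
  if (is.nan(yFrom) || is.nan(yTo))
    stop("indeterminate limit: both inputs infinite")
  if (yTo == 0) stop("denominator response is zero")
  yFrom / yTo
}
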