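## Two-stage nonlinear least-squares inference for the steady-state model.

.DYNRANGE_MIN <- 1.2  # below this fold-range kappa/alpha are unidentifiable

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} computed on the scale of the supplied
#' values (the package default is the linear fluorescence scale).
#'
#' @param observed,predicted numeric vectors of equal length >= 2
#' @return R-squared (<= 1; can be negative for a fit worse than the mean)
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
rSquared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must have equal length >= 2")
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ssTot
}

## residual helper on the requested scale
.scaleResid <- function(obs, pred, scale) {
  if (scale == "log10") log10(pred) - log10(obs) else pred - obs
}

.fitOptions <- function(scale = c("linear", "log10"), relaxAlpha = FALSE,
                        maxIter = 200L) {
  scale <- match.arg(scale)
  list(scale = scale, alphaMin = if (relaxAlpha) 1e-6 else 1,
       maxIter = as.integer(maxIter))
}

#' Fit the single-guide steady-state response to an induction curve
#'
#' Least-squares estimation of the single-guide response.  The model is
#' algebraically equivalent to
#' \deqn{y = A + \frac{y_{max} - A}{1 + \kappa_R x_R},\qquad
#'       A = y_{min} + (y_{max}-y_{min})/\alpha_R,}
#' so a single induction curve identifies exactly three quantities - the
#' fully repressed floor \eqn{A}, the ceiling \eqn{y_{max}} and
#' \eqn{\kappa_R} - while \eqn{y_{min}} and \eqn{\alpha_R} trade off along an
#' exact ridge.  The floor is a measured quantity, not a curve-shape
#' parameter:
#' \itemize{
#'   \item supply it via \code{yMin} (the measured fully repressed output,
#'     e.g. from a saturating-repression control) and \eqn{\alpha_R} becomes
#'     identifiable: \eqn{\alpha_R = (y_{max}-y_{min})/(A-y_{min})};
#'   \item with \code{yMin = NULL} (default) the identifiable triple is fit
#'     and reported under the convention \code{yMin = 0},
#'     \code{alphaR = yMax/A}; \code{yMin} and \code{alphaR} are flagged as
#'     jointly (ridge-) unidentifiable.
#' }
#' Either way the fitted curve itself, \code{kappaR}, \code{yMax} and the
#' floor are the same.
#'
#' Initialization: floor from min(y), yMax from max(y), kappaR from
#' 1/median(x > 0).  Bounds keep all parameters positive and (unless
#' \code{relaxAlpha}) the implied alphaR >= 1.  The objective is unweighted
#' least squares on the linear fluorescence scale by default;
#' \code{scale = "log10"} switches to log-scale residuals.
#'
#' A curve whose outputs span less than a 1.2-fold range carries no
#' information about kappaR/alphaR; both are flagged unidentifiable.
#' Non-convergence is flagged on the result, never thrown.
#'
#' @param curve an \linkS4class{InductionCurve} with >= 4 points
#' @param yMin measured fully repressed floor (au), or NULL
#' @param scale residual scale, "linear" (default) or "log10"
#' @param relaxAlpha allow the implied alpha below 1 (exploratory fits; by
#'   default alpha >= 1 since dCas9 occupancy alone cannot activate)
#' @param maxIter Levenberg-Marquardt iteration cap
#' @return a \linkS4class{FitResult}
#' @examples
#' truth <- SteadyStateParams(16, 6800, 0.043, 120)
#' cur <- genInductionCurve(truth, defaultActivityLevels())
#' fitSingle(cur, yMin = 16)   # recovers kappaR = 0.043, alphaR = 120
#' @importFrom minpack.lm nls.lm nls.lm.control
#' @export
fitSingle <- function(curve, yMin = NULL, scale = c("linear", "log10"),
                      relaxAlpha = FALSE, maxIter = 200L) {
  stopifnot(is(curve, "InductionCurve"))
  opt <- .fitOptions(scale, relaxAlpha, maxIter)
  x <- curve@x
  y <- curve@yMean
  if (length(x) < 4) stop("need >= 4 points to fit the response model")

  unident <- character()
  if (max(y) / min(y) < .DYNRANGE_MIN) unident <- c("kappaR", "alphaR")

  xPos <- x[x > 0]
  k0 <- if (length(xPos)) 1 / stats::median(xPos) else 1
  yMinFixed <- !is.null(yMin)
  if (yMinFixed && (yMin < 0 || yMin >= max(y)))
    stop("yMin must be in [0, max(y))")
  base <- if (yMinFixed) yMin else 0
  ## parameters: (floor A, ceiling lift dC = yMax - A, kappaR); the implied
  ## alpha = 1 + dC/(A - base) is automatically >= 1 for dC >= 0, A > base
  floor0 <- (base + min(y)) / 2 + 1e-9
  start <- c(A = floor0, dC = max(y) - floor0, kappaR = k0)
  lower <- c(base + 1e-12, if (opt$alphaMin < 1) -Inf else 1e-9, 1e-12)

  resid <- function(p) {
    pred <- p[1] + p[2] / (1 + p[3] * x)
    pen <- if (p[1] + p[2] <= base) 1e6 * (base - p[1] - p[2]) + 1 else 0
    .scaleResid(y, pred, opt$scale) + pen
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = opt$maxIter,
                                         ftol = 1e-15, ptol = 1e-15))
  A <- fit$par[1]; yMaxHat <- fit$par[1] + fit$par[2]; kHat <- fit$par[3]
  yMinHat <- if (yMinFixed) yMin else 0
  alphaHat <- (yMaxHat - yMinHat) / (A - yMinHat)
  if (!yMinFixed) unident <- unique(c(unident, "yMin", "alphaR"))
  params <- SteadyStateParams(yMin = yMinHat, yMax = yMaxHat,
                              kappaR = kHat, alphaR = max(alphaHat, 1e-12))
  pred <- responseSingle(x, params)
  new("FitResult", params = params,
      freeNames = c("yMin", "yMax", "kappaR", "alphaR")[
        c(!yMinFixed, TRUE, TRUE, TRUE)],
      rSquared = if (stats::var(y) > 0) rSquared(y, pred) else NA_real_,
      residuals = y - pred,
      converged = fit$info %in% 1:3 && !any(c("kappaR") %in% unident),
      nIter = as.integer(fit$niter), unidentifiable = unident)
}

#' Fit the dual-guide response grid with single-guide parameters frozen
#'
#' Second stage of the inference: (kappaD, alphaD) are estimated by least
#' squares over all grid cells while (yMin, yMax, kappaR, alphaR) are held
#' fixed at the values previously fit to the single-guide induction curve.
#' The fixed parameters pass through to the result untouched.
#'
#' @param grid a \linkS4class{ResponseGrid}
#' @param fixed a \linkS4class{SteadyStateParams} supplying the frozen
#'   single-guide parameters
#' @inheritParams fitSingle
#' @return a \linkS4class{FitResult}; residuals are ordered column-major over
#'   the grid (xR varying fastest)
#' @export
fitDual <- function(grid, fixed, scale = c("linear", "log10"),
                    relaxAlpha = FALSE, maxIter = 200L) {
  stopifnot(is(grid, "ResponseGrid"), is(fixed, "SteadyStateParams"))
  opt <- .fitOptions(scale, relaxAlpha, maxIter)
  xR <- rep(grid@xRLevels, times = length(grid@xDLevels))
  xD <- rep(grid@xDLevels, each = length(grid@xRLevels))
  y <- as.vector(grid@y)
  if (any(y <= 0)) stop("grid outputs must be > 0")

  unident <- character()
  if (all(xD == 0)) unident <- c("kappaD", "alphaD")

  xDPos <- xD[xD > 0]
  start <- c(kappaD = if (length(xDPos)) 1 / stats::median(xDPos) else 1,
             alphaD = max(1.5, opt$alphaMin))
  lower <- c(1e-12, opt$alphaMin)

  yMin <- fixed@yMin; yMax <- fixed@yMax
  kR <- fixed@kappaR; aR <- fixed@alphaR
  resid <- function(p) {
    pred <- .responseKernel(kR * xR, p[1] * xD, yMin, yMax, aR, p[2])
    .scaleResid(y, pred, opt$scale)
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = opt$maxIter,
                                         ftol = 1e-15, ptol = 1e-15))
  params <- SteadyStateParams(yMin = yMin, yMax = yMax, kappaR = kR,
                              alphaR = aR, kappaD = fit$par[1],
                              alphaD = fit$par[2])
  pred <- responseDual(xR, xD, params)
  new("FitResult", params = params, freeNames = c("kappaD", "alphaD"),
      rSquared = if (stats::var(y) > 0) rSquared(y, pred) else NA_real_,
      residuals = y - pred,
      converged = fit$info %in% 1:3 && length(unident) == 0L,
      nIter = as.integer(fit$niter), unidentifiable = unident)
}

#' Estimate fold-repression alpha from on/off measurements
#'
#' alpha is the ratio of the mean output with the guide uninduced (off) to the
#' mean with the guide fully induced (on).  The uncertainty is first-order
#' propagated from the replicate standard deviations:
#' \eqn{\sigma = |A/B|\sqrt{(\sigma_A/A)^2 + (\sigma_B/B)^2}} with A = off
#' mean, B = on mean.
#'
#' @param meanOff,sdOff mean and SD of the uninduced measurements (au)
#' @param meanOn,sdOn mean and SD of the fully induced measurements (au)
#' @return an \linkS4class{AlphaEstimate}
#' @examples
#' alphaFromOnOff(100, 10, 50, 5)  # 2.0 +/- 0.283
#' @export
alphaFromOnOff <- function(meanOff, sdOff, meanOn, sdOn) {
  if (meanOn <= 0) stop("meanOn must be > 0")
  if (meanOff <= 0) stop("meanOff must be > 0")
  a <- meanOff / meanOn
  s <- abs(a) * sqrt((sdOff / meanOff)^2 + (sdOn / meanOn)^2)
  new("AlphaEstimate", alpha = a, sigma = s)
}

#' Relative expression of a circuit against a guide-free reference
#'
#' The ratio of the fluorescence obtained in the absence of any guide RNA to
#' the fluorescence obtained when the guides are expressed, with the same
#' propagated uncertainty as \code{\link{alphaFromOnOff}}.
#'
#' @param refMean,refSd guide-free reference mean and SD (au)
#' @param circuitMean,circuitSd circuit mean and SD (au)
#' @return an \linkS4class{AlphaEstimate}
#' @export
relativeExpression <- function(refMean, refSd, circuitMean, circuitSd) {
  if (circuitMean <= 0) stop("circuitMean must be > 0")
  alphaFromOnOff(refMean, refSd, circuitMean, circuitSd)
}
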