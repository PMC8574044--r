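## Ratiometric interpretation of two-dimensional response grids.
##
## In the saturating regime (kappa_R x_R >> 1 and kappa_D x_D >> 1) the
## dual-guide response depends on the inputs only through their ratio:
##   y -> (ymax - ymin) (kappaR/alphaR + kappaD r / alphaD) /
##                      (kappaR + kappaD r) + ymin,  r = xD/xR,
## which is the analytic basis for reading the circuit as a ratio sensor.

#' Collapse a response grid onto the input-ratio axis
#'
#' One point per grid cell with both inputs positive, at ratio xD/xR; cells
#' with a zero input are excluded and counted.  The dynamic range is
#' max(y)/min(y) over retained points with ratio >= 1 (mirroring the
#' convention of graying out ratios below 1).
#'
#' @param grid a \linkS4class{ResponseGrid} with at least one cell where both
#'   inputs are positive
#' @return a \linkS4class{RatioResponse}
#' @export
collapseToRatio <- function(grid) {
  stopifnot(is(grid, "ResponseGrid"))
  nR <- length(grid@xRLevels)
  nD <- length(grid@xDLevels)
  row <- rep(seq_len(nR), times = nD)
  col <- rep(seq_len(nD), each = nR)
  xR <- grid@xRLevels[row]
  xD <- grid@xDLevels[col]
  y <- as.vector(grid@y)
  ok <- xR > 0 & xD > 0
  if (!any(ok)) stop("no grid cell has both inputs positive")
  ratio <- xD[ok] / xR[ok]
  yOk <- y[ok]
  ge1 <- ratio >= 1
  dr <- if (any(ge1)) max(yOk[ge1]) / min(yOk[ge1]) else NA_real_
  new("RatioResponse", ratio = ratio, y = yOk,
      sourceCells = data.frame(row = row[ok], col = col[ok],
                               xR = xR[ok], xD = xD[ok]),
      dynamicRange = dr, excludedCells = sum(!ok))
}

#' Log-ratio span of the transition region
#'
#' The log10 extent of the ratio interval over which the output traverses the
#' central (1 - 2 * thresholdFraction) of its dynamic range.  Points are
#' aggregated into log-spaced ratio bins (5 per decade) by their median, the
#' binned response is checked for monotonicity, and the two crossing ratios
#' are found by interpolating the binned medians against log10(ratio).  When
#' the binned medians are not monotone the span is computed on their monotone
#' (cumulative-extreme) envelope and the result is flagged.
#'
#' @param resp a \linkS4class{RatioResponse} with >= 3 points
#' @param thresholdFraction the excluded tail fraction at each end of the
#'   response range (default 0.05: the span covers 5\% to 95\%)
#' @param binsPerDecade log-spaced bin density for median aggregation
#' @return a list with \code{span} (decades, NA when the response is flat),
#'   \code{monotone} (logical) and \code{flag} ("ok", "nonmonotone" or
#'   "undefined")
#' @export
ratioSpan <- function(resp, thresholdFraction = 0.05, binsPerDecade = 5) {
  stopifnot(is(resp, "RatioResponse"))
  if (length(resp@ratio) < 3) stop("need >= 3 points")
  if (thresholdFraction <= 0 || thresholdFraction >= 0.5)
    stop("thresholdFraction must be in (0, 0.5)")
  lr <- log10(resp@ratio)
  width <- 1 / binsPerDecade
  bins <- floor(lr / width)
  med <- tapply(resp@y, bins, stats::median)
  ctr <- (as.numeric(names(med)) + 0.5) * width
  ord <- order(ctr)
  ctr <- ctr[ord]; med <- as.numeric(med)[ord]

  if (max(med) == min(med))
    return(list(span = NA_real_, monotone = TRUE, flag = "undefined"))

  increasing <- med[length(med)] >= med[1]
  mono <- if (increasing) all(diff(med) >= 0) else all(diff(med) <= 0)
  env <- med
  if (!mono) env <- if (increasing) cummax(med) else cummin(med)

  lo <- min(env) + thresholdFraction * (max(env) - min(env))
  hi <- min(env) + (1 - thresholdFraction) * (max(env) - min(env))
  cross <- function(level) {
    # first bin-center log-ratio at which the envelope crosses `level`
    if (!increasing) { envv <- rev(env); ctrv <- rev(ctr) }
    else { envv <- env; ctrv <- ctr }
    i <- which(envv >= level)[1]
    if (i == 1L) return(ctrv[1])
    stats::approx(envv[(i - 1):i], ctrv[(i - 1):i], xout = level,
                  ties = "ordered")$y
  }
  span <- abs(cross(hi) - cross(lo))
  list(span = span, monotone = mono, flag = if (mono) "ok" else "nonmonotone")
}
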