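## Accessor generics and methods, plus show methods.

#' @name accessors
#' @title Accessors for crisprDerep classes
#' @description Small accessor generics exposing the slots of the package's
#'   data classes without direct slot access.
#' @param x an object of the documented class
#' @return the corresponding slot value
NULL

#' @rdname accessors
#' @export
setGeneric("yMin", function(x) standardGeneric("yMin"))
#' @rdname accessors
#' @export
setGeneric("yMax", function(x) standardGeneric("yMax"))
#' @rdname accessors
#' @export
setGeneric("kappaR", function(x) standardGeneric("kappaR"))
#' @rdname accessors
#' @export
setGeneric("kappaD", function(x) standardGeneric("kappaD"))
#' @rdname accessors
#' @export
setGeneric("alphaR", function(x) standardGeneric("alphaR"))
#' @rdname accessors
#' @export
setGeneric("alphaD", function(x) standardGeneric("alphaD"))

#' @rdname accessors
setMethod("yMin", "SteadyStateParams", function(x) x@yMin)
#' @rdname accessors
setMethod("yMax", "SteadyStateParams", function(x) x@yMax)
#' @rdname accessors
setMethod("kappaR", "SteadyStateParams", function(x) x@kappaR)
#' @rdname accessors
setMethod("kappaD", "SteadyStateParams", function(x) x@kappaD)
#' @rdname accessors
setMethod("alphaR", "SteadyStateParams", function(x) x@alphaR)
#' @rdname accessors
setMethod("alphaD", "SteadyStateParams", function(x) x@alphaD)

#' @rdname accessors
#' @export
setGeneric("xValues", function(x) standardGeneric("xValues"))
#' @rdname accessors
#' @export
setGeneric("yMean", function(x) standardGeneric("yMean"))
#' @rdname accessors
#' @export
setGeneric("ySd", function(x) standardGeneric("ySd"))
#' @rdname accessors
#' @export
setGeneric("nReps", function(x) standardGeneric("nReps"))
#' @rdname accessors
#' @export
setGeneric("replicateDraws", function(x) standardGeneric("replicateDraws"))

#' @rdname accessors
setMethod("xValues", "InductionCurve", function(x) x@x)
#' @rdname accessors
setMethod("yMean", "InductionCurve", function(x) x@yMean)
#' @rdname accessors
setMethod("ySd", "InductionCurve", function(x) x@ySd)
#' @rdname accessors
setMethod("nReps", "InductionCurve", function(x) x@nReps)
#' @rdname accessors
setMethod("replicateDraws", "InductionCurve", function(x) x@reps)

#' @rdname accessors
#' @export
setGeneric("xRLevels", function(x) standardGeneric("xRLevels"))
#' @rdname accessors
#' @export
setGeneric("xDLevels", function(x) standardGeneric("xDLevels"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
setMethod("xRLevels", "ResponseGrid", function(x) x@xRLevels)
#' @rdname accessors
setMethod("xDLevels", "ResponseGrid", function(x) x@xDLevels)
#' @rdname accessors
setMethod("gridValues", "ResponseGrid", function(x) x@y)
#' @rdname accessors
setMethod("ySd", "ResponseGrid", function(x) x@ySd)

#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setGeneric("rSquaredOf", function(x) standardGeneric("rSquaredOf"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("freeNames", function(x) standardGeneric("freeNames"))
#' @rdname accessors
#' @export
setGeneric("unidentifiable", function(x) standardGeneric("unidentifiable"))
#' @rdname accessors
#' @export
setGeneric("nIter", function(x) standardGeneric("nIter"))

#' @rdname accessors
setMethod("fitParams", "FitResult", function(x) x@params)
#' @rdname accessors
setMethod("rSquaredOf", "FitResult", function(x) x@rSquared)
#' @rdname accessors
setMethod("converged", "FitResult", function(x) x@converged)
#' @rdname accessors
setMethod("freeNames", "FitResult", function(x) x@freeNames)
#' @rdname accessors
setMethod("unidentifiable", "FitResult", function(x) x@unidentifiable)
#' @rdname accessors
setMethod("nIter", "FitResult", function(x) x@nIter)
#' @rdname accessors
#' @param object a FitResult
#' @param ... unused
#' @importFrom stats residuals
#' @exportMethod residuals
setMethod("residuals", "FitResult", function(object, ...) object@residuals)

#' @rdname accessors
#' @export
setGeneric("alphaValue", function(x) standardGeneric("alphaValue"))
#' @rdname accessors
#' @export
setGeneric("alphaSigma", function(x) standardGeneric("alphaSigma"))
#' @rdname accessors
setMethod("alphaValue", "AlphaEstimate", function(x) x@alpha)
#' @rdname accessors
setMethod("alphaSigma", "AlphaEstimate", function(x) x@sigma)

#' @rdname accessors
#' @export
setGeneric("spacer", function(x) standardGeneric("spacer"))
#' @rdname accessors
#' @export
setGeneric("strandOf", function(x) standardGeneric("strandOf"))
#' @rdname accessors
#' @export
setGeneric("protoRange", function(x) standardGeneric("protoRange"))
#' @rdname accessors
#' @export
setGeneric("pamRange", function(x) standardGeneric("pamRange"))
#' @rdname accessors
setMethod("spacer", "GuideSite", function(x) x@spacer)
#' @rdname accessors
setMethod("strandOf", "GuideSite", function(x) x@strand)
#' @rdname accessors
setMethod("protoRange", "GuideSite", function(x) c(x@protoStart, x@protoEnd))
#' @rdname accessors
setMethod("pamRange", "GuideSite", function(x) c(x@pamStart, x@pamEnd))

#' @rdname accessors
#' @export
setGeneric("gapBp", function(x) standardGeneric("gapBp"))
#' @rdname accessors
#' @export
setGeneric("pamsFacing", function(x) standardGeneric("pamsFacing"))
#' @rdname accessors
#' @export
setGeneric("competitive", function(x) standardGeneric("competitive"))
#' @rdname accessors
#' @export
setGeneric("sgdRepressionRisk", function(x) standardGeneric("sgdRepressionRisk"))
#' @rdname accessors
setMethod("gapBp", "PairClassification", function(x) x@gapBp)
#' @rdname accessors
setMethod("pamsFacing", "PairClassification", function(x) x@pamsFacing)
#' @rdname accessors
setMethod("competitive", "PairClassification", function(x) x@competitive)
#' @rdname accessors
setMethod("sgdRepressionRisk", "PairClassification",
          function(x) x@sgdRepressionRisk)

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("mrnaLevels", function(x) standardGeneric("mrnaLevels"))
#' @rdname accessors
#' @export
setGeneric("fluorLevels", function(x) standardGeneric("fluorLevels"))
#' @rdname accessors
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))
#' @rdname accessors
setMethod("timePoints", "Trajectory", function(x) x@time)
#' @rdname accessors
setMethod("mrnaLevels", "Trajectory", function(x) x@mrna)
#' @rdname accessors
setMethod("fluorLevels", "Trajectory", function(x) x@fluor)
#' @rdname accessors
setMethod("phaseLabels", "Trajectory", function(x) x@phase)

#' @rdname accessors
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))
#' @rdname accessors
#' @export
setGeneric("dynamicRange", function(x) standardGeneric("dynamicRange"))
#' @rdname accessors
#' @export
setGeneric("excludedCells", function(x) standardGeneric("excludedCells"))
#' @rdname accessors
#' @export
setGeneric("sourceCells", function(x) standardGeneric("sourceCells"))
#' @rdname accessors
setMethod("ratioValues", "RatioResponse", function(x) x@ratio)
#' @rdname accessors
setMethod("yMean", "RatioResponse", function(x) x@y)
#' @rdname accessors
setMethod("dynamicRange", "RatioResponse", function(x) x@dynamicRange)
#' @rdname accessors
setMethod("excludedCells", "RatioResponse", function(x) x@excludedCells)
#' @rdname accessors
setMethod("sourceCells", "RatioResponse", function(x) x@sourceCells)

## show methods -------------------------------------------------------------

.fmtNA <- function(x) if (is.na(x)) "NA" else format(x, digits = 6)

setMethod("show", "SteadyStateParams", function(object) {
  cat("SteadyStateParams (observable scale)\n")
  cat(sprintf("  yMin=%s  yMax=%s\n", .fmtNA(object@yMin), .fmtNA(object@yMax)))
  cat(sprintf("  kappaR=%s  alphaR=%s\n",
              .fmtNA(object@kappaR), .fmtNA(object@alphaR)))
  if (!is.na(object@kappaD))
    cat(sprintf("  kappaD=%s  alphaD=%s\n",
                .fmtNA(object@kappaD), .fmtNA(object@alphaD)))
})

setMethod("show", "KineticParams", function(object) {
  cat("KineticParams (mRNA scale)\n")
  cat(sprintf("  betaM=%s beta=%s deltaM=%s\n", .fmtNA(object@betaM),
              .fmtNA(object@beta), .fmtNA(object@deltaM)))
  cat(sprintf("  KR=%s KD=%s alphaR=%s alphaD=%s\n", .fmtNA(object@KR),
              .fmtNA(object@KD), .fmtNA(object@alphaR), .fmtNA(object@alphaD)))
})

setMethod("show", "InductionCurve", function(object) {
  cat(sprintf("InductionCurve: %d levels, x in [%g, %g] au, %d rep(s)\n",
              length(object@x), min(object@x), max(object@x), object@nReps))
})

setMethod("show", "ResponseGrid", function(object) {
  cat(sprintf("ResponseGrid: %d xR levels x %d xD levels\n",
              length(object@xRLevels), length(object@xDLevels)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: free = {%s}, R^2 = %s, converged = %s (%d iter)\n",
              paste(object@freeNames, collapse = ", "),
              .fmtNA(object@rSquared), object@converged, object@nIter))
  if (length(object@unidentifiable))
    cat(sprintf("  unidentifiable: %s\n",
                paste(object@unidentifiable, collapse = ", ")))
  show(object@params)
})

setMethod("show", "AlphaEstimate", function(object) {
  cat(sprintf("AlphaEstimate: %.6g +/- %.6g\n", object@alpha, object@sigma))
})

setMethod("show", "HillTransfer", function(object) {
  cat(sprintf(
    "HillTransfer[%s]: basal=%g maximal=%g halfMax=%g uM hillN=%g\n",
    object@inducerName, object@basal, object@maximal, object@halfMax,
    object@hillN))
})

setMethod("show", "GuideSite", function(object) {
  cat(sprintf("GuideSite (%s strand): protospacer %d-%d, PAM %d-%d\n",
              object@strand, object@protoStart, object@protoEnd,
              object@pamStart, object@pamEnd))
  cat(sprintf("  spacer: %s\n", object@spacer))
})

setMethod("show", "PairClassification", function(object) {
  cat(sprintf(
    "PairClassification [%s]: gap %d bp, PAMs %s, %s; sgD repression risk: %s\n",
    object@context, object@gapBp,
    if (object@pamsFacing) "facing" else "not facing",
    object@competitive, object@sgdRepressionRisk))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d samples over [%g, %g] min, %d phase(s)\n",
              length(object@time), min(object@time), max(object@time),
              length(unique(object@phase))))
})

setMethod("show", "RatioResponse", function(object) {
  cat(sprintf(
    "RatioResponse: %d points, ratio in [%.3g, %.3g], DR %.3g, %d excluded\n",
    length(object@ratio), min(object@ratio), max(object@ratio),
    object@dynamicRange, object@excludedCells))
})
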