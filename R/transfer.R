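## Inducer-concentration <-> promoter-activity transfer functions.
##
## The inducible systems (IPTG/P_Tac, vanillic acid/P_Van, choline/P_BetI)
## report their activity in fluorescence-calibrated au; a Hill form stands in
## for the separately measured response functions.  The shipped presets are
## placeholder parameter sets: every downstream stage also accepts
## activity-unit inputs directly, so the presets are never load-bearing.

#' Forward transfer: inducer concentration to promoter activity
#'
#' @param conc inducer concentration (uM, >= 0); vectorized
#' @param transfer a \linkS4class{HillTransfer}
#' @return promoter activity (au)
#' @export
hillForward <- function(conc, transfer) {
  stopifnot(is(transfer, "HillTransfer"))
  if (any(conc < 0)) stop("conc must be >= 0")
  cn <- conc^transfer@hillN
  transfer@basal + (transfer@maximal - transfer@basal) *
    cn / (transfer@halfMax^transfer@hillN + cn)
}

#' Inverse transfer: promoter activity back to inducer concentration
#'
#' Algebraic inversion of the Hill form, valid strictly inside
#' (basal, maximal).
#'
#' @param activity promoter activity (au), in the open interval
#'   (basal, maximal); vectorized
#' @param transfer a \linkS4class{HillTransfer}
#' @return inducer concentration (uM)
#' @export
hillInverse <- function(activity, transfer) {
  stopifnot(is(transfer, "HillTransfer"))
  if (any(activity <= transfer@basal) || any(activity >= transfer@maximal))
    stop("activity must lie strictly between basal and maximal")
  frac <- (activity - transfer@basal) / (transfer@maximal - activity)
  transfer@halfMax * frac^(1 / transfer@hillN)
}

#' Calibrate a Hill transfer function from measured points
#'
#' Least-squares Hill fit of concentration/activity pairs.  Requires at least
#' 4 points spanning more than a 2-fold activity range; otherwise the result
#' carries an \code{unidentifiable} attribute and the returned parameters are
#' the initialization.
#'
#' @param concs inducer concentrations (uM)
#' @param activities measured promoter activities (au)
#' @param inducerName label stored on the result
#' @return a \linkS4class{HillTransfer}; attribute \code{unidentifiable} is
#'   TRUE when the data could not constrain the fit
#' @importFrom minpack.lm nls.lm nls.lm.control
#' @export
calibrateHill <- function(concs, activities, inducerName = "") {
  if (length(concs) != length(activities) || length(concs) < 4)
    stop("need >= 4 concentration/activity points")
  rng <- max(activities) / max(min(activities), .Machine$double.eps)
  start <- c(basal = max(min(activities), 1e-9),
             dy = max(max(activities) - min(activities), 1e-9),
             halfMax = max(stats::median(concs[concs > 0]), 1e-9),
             hillN = 1)
  if (rng <= 2) {
    out <- HillTransfer(start[1], start[1] + start[2], start[3], start[4],
                        inducerName)
    attr(out, "unidentifiable") <- TRUE
    return(out)
  }
  resid <- function(p) {
    cn <- concs^p[4]
    p[1] + p[2] * cn / (p[3]^p[4] + cn) - activities
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = c(0, 1e-9, 1e-12, 1e-3), fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- fit$par
  out <- HillTransfer(p[1], p[1] + p[2], p[3], p[4], inducerName)
  attr(out, "unidentifiable") <- FALSE
  out
}

#' Named transfer-function presets
#'
#' Placeholder Hill parameter sets for the three inducible systems used to
#' drive guide expression (IPTG -> P_Tac, vanillic acid -> P_Van, choline ->
#' P_BetI).  The shapes are plausible for E. coli marionette-style sensors but
#' are not measured values; treat them as synthetic conventions for laying
#' out simulated experiments.
#'
#' @param name one of "IPTG", "Van", "Chol"
#' @return a \linkS4class{HillTransfer}
#' @export
transferPreset <- function(name = c("IPTG", "Van", "Chol")) {
  name <- match.arg(name)
  path <- system.file("extdata", "transfer_presets.json",
                      package = "crisprDerep", mustWork = TRUE)
  presets <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  p <- presets[[name]]
  HillTransfer(p$basal, p$maximal, p$half_max, p$hill_n, p$inducer)
}

#' Inducer concentration layouts for simulated titrations
#'
#' The concentration series used for laying out synthetic experiments:
#' 12-level IPTG and choline titrations, a 12-level vanillic acid titration,
#' and the 11 x 7 Van x Chol dual-induction grid.
#'
#' @param name layout name
#' @return for the titrations, a numeric vector of concentrations (uM); for
#'   "dual_grid_7x11", a list with elements \code{van} (11 levels, uM) and
#'   \code{chol} (7 levels, uM)
#' @export
inducerLayout <- function(name = c("iptg_titration", "van_titration",
                                   "chol_titration", "dual_grid_7x11")) {
  name <- match.arg(name)
  van <- c(0, 0.195, 0.391, 0.781, 1.56, 3.13, 6.25, 12.5, 25, 50, 100)
  switch(name,
    iptg_titration = c(0, 0.977, 1.95, 3.91, 7.81, 15.6, 31.3, 62.5, 125,
                       250, 500, 1000),
    van_titration = c(0, 0.0977, van[-1]),
    chol_titration = c(0, 9.77, 19.5, 39.1, 78.1, 156, 313, 625, 1250, 2500,
                       5000, 10000),
    dual_grid_7x11 = list(van = van,
                          chol = c(0, 37.0, 111, 333, 1000, 3000, 9000))
  )
}
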