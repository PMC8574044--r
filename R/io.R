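## File I/O: CSV schemas, FASTA ingestion, JSON parameter serialization.
##
## CSV files are UTF-8, header row, "." decimal separator.  Schemas:
##   curve: input_au,fluorescence_au[,sd_au,n_reps]
##   grid (long): x_R_au,x_D_au,fluorescence_au[,sd_au]
##   trajectory: time_min,mrna,fluorescence_au,phase

.requireCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s file is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
}

#' Read / write induction-curve CSV files
#'
#' @param path file path
#' @return \code{readCurve}: an \linkS4class{InductionCurve}
#' @export
readCurve <- function(path) {
  df <- utils::read.csv(path)
  .requireCols(df, c("input_au", "fluorescence_au"), "curve")
  InductionCurve(
    x = df$input_au, yMean = df$fluorescence_au,
    ySd = if ("sd_au" %in% names(df)) df$sd_au else numeric(),
    nReps = if ("n_reps" %in% names(df)) as.integer(df$n_reps[1]) else 1L)
}

#' @rdname readCurve
#' @param curve an \linkS4class{InductionCurve}
#' @return \code{writeCurve}: the path, invisibly
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "InductionCurve"))
  df <- data.frame(input_au = curve@x, fluorescence_au = curve@yMean)
  if (length(curve@ySd)) df$sd_au <- curve@ySd
  df$n_reps <- curve@nReps
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write response-grid CSV files (long format)
#'
#' The long format carries one row per grid cell; on reading, cells are
#' reassembled into the level-by-level matrix.
#'
#' @param path file path
#' @return \code{readGrid}: a \linkS4class{ResponseGrid}
#' @export
readGrid <- function(path) {
  df <- utils::read.csv(path)
  .requireCols(df, c("x_R_au", "x_D_au", "fluorescence_au"), "grid")
  xR <- sort(unique(df$x_R_au))
  xD <- sort(unique(df$x_D_au))
  y <- matrix(NA_real_, length(xR), length(xD))
  hasSd <- "sd_au" %in% names(df)
  ySd <- if (hasSd) y else matrix(numeric(), 0, 0)
  i <- match(df$x_R_au, xR)
  j <- match(df$x_D_au, xD)
  y[cbind(i, j)] <- df$fluorescence_au
  if (hasSd) ySd[cbind(i, j)] <- df$sd_au
  if (anyNA(y)) stop("grid file does not cover all level combinations")
  ResponseGrid(xR, xD, y, ySd)
}

#' @rdname readGrid
#' @param grid a \linkS4class{ResponseGrid}
#' @return \code{writeGrid}: the path, invisibly
#' @export
writeGrid <- function(grid, path) {
  stopifnot(is(grid, "ResponseGrid"))
  nR <- length(grid@xRLevels); nD <- length(grid@xDLevels)
  df <- data.frame(x_R_au = rep(grid@xRLevels, times = nD),
                   x_D_au = rep(grid@xDLevels, each = nR),
                   fluorescence_au = as.vector(grid@y))
  if (nrow(grid@ySd)) df$sd_au <- as.vector(grid@ySd)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns: time_min, mrna, fluorescence_au, phase.
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param path file path
#' @return the path, invisibly
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  utils::write.csv(
    data.frame(time_min = trajectory@time, mrna = trajectory@mrna,
               fluorescence_au = trajectory@fluor, phase = trajectory@phase),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a reference sequence from FASTA
#'
#' Single-line or wrapped sequences are accepted; bases are uppercased on
#' ingestion.
#'
#' @param path FASTA file path
#' @param which record index (default: first)
#' @return a character string of the sequence
#' @export
readFastaRef <- function(path, which = 1L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < which) stop("FASTA record ", which, " not found")
  toupper(as.character(set[[which]]))
}

#' Serialize model parameters to / from flat JSON
#'
#' Observable-scale parameters map to keys y_min, y_max, kappa_R, kappa_D,
#' alpha_R, alpha_D (the dual-guide keys are omitted for single-guide sets);
#' kinetic parameters map to beta_m, beta, delta_m, K_R, K_D, alpha_R,
#' alpha_D.
#'
#' @param params a \linkS4class{SteadyStateParams} or
#'   \linkS4class{KineticParams}
#' @param path optional file path; when NULL the JSON string is returned
#' @return \code{paramsToJson}: the JSON string (invisibly when written to a
#'   file)
#' @export
paramsToJson <- function(params, path = NULL) {
  obj <- if (is(params, "SteadyStateParams")) {
    o <- list(y_min = params@yMin, y_max = params@yMax,
              kappa_R = params@kappaR, alpha_R = params@alphaR)
    if (!is.na(params@kappaD)) {
      o$kappa_D <- params@kappaD
      o$alpha_D <- params@alphaD
    }
    o
  } else if (is(params, "KineticParams")) {
    list(beta_m = params@betaM, beta = params@beta, delta_m = params@deltaM,
         K_R = params@KR, K_D = params@KD, alpha_R = params@alphaR,
         alpha_D = params@alphaD)
  } else stop("unsupported parameter class")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname paramsToJson
#' @param json a JSON string or path to a JSON file
#' @return \code{paramsFromJson}: the reconstructed parameter object (class
#'   chosen from the key set)
#' @export
paramsFromJson <- function(json) {
  o <- jsonlite::fromJSON(json)
  if (all(c("beta_m", "delta_m") %in% names(o))) {
    KineticParams(betaM = o$beta_m, beta = o$beta, deltaM = o$delta_m,
                  KR = o$K_R, KD = o$K_D, alphaR = o$alpha_R,
                  alphaD = o$alpha_D)
  } else if (all(c("y_min", "y_max", "kappa_R", "alpha_R") %in% names(o))) {
    SteadyStateParams(
      yMin = o$y_min, yMax = o$y_max, kappaR = o$kappa_R,
      alphaR = o$alpha_R,
      kappaD = if (is.null(o$kappa_D)) NA_real_ else o$kappa_D,
      alphaD = if (is.null(o$alpha_D)) NA_real_ else o$alpha_D)
  } else stop("unrecognized parameter JSON: missing required keys")
}

#' Serialize an induction schedule to / from JSON
#'
#' The JSON object holds an \code{events} array of \{t, x_R, x_D\} records
#' and the total \code{duration} (min).
#'
#' @param schedule an \linkS4class{InductionSchedule}
#' @param path optional output path
#' @return \code{scheduleToJson}: the JSON string
#' @export
scheduleToJson <- function(schedule, path = NULL) {
  stopifnot(is(schedule, "InductionSchedule"))
  ev <- schedule@events
  obj <- list(events = data.frame(t = ev$time, x_R = ev$xR, x_D = ev$xD),
              duration = schedule@duration)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname scheduleToJson
#' @param json a JSON string or file path
#' @return \code{scheduleFromJson}: an \linkS4class{InductionSchedule}
#' @export
scheduleFromJson <- function(json) {
  o <- jsonlite::fromJSON(json)
  if (is.null(o$events) || is.null(o$duration))
    stop("schedule JSON needs 'events' and 'duration'")
  InductionSchedule(times = o$events$t, xR = o$events$x_R, xD = o$events$x_D,
                    duration = o$duration)
}

#' Write a guide-pair verdict as a BED-like TSV plus JSON
#'
#' The TSV is 1-based with columns ref, start, end, strand, role, verdict.
#'
#' @param siteR,siteD the classified \linkS4class{GuideSite}s
#' @param cls the \linkS4class{PairClassification}
#' @param refName reference sequence name
#' @param tsvPath,jsonPath output paths (either may be NULL to skip)
#' @return the verdict as a list, invisibly
#' @export
writePairVerdict <- function(siteR, siteD, cls, refName = "ref",
                             tsvPath = NULL, jsonPath = NULL) {
  rows <- data.frame(
    ref = refName,
    start = c(.footprint(siteR)[1], .footprint(siteD)[1]),
    end = c(.footprint(siteR)[2], .footprint(siteD)[2]),
    strand = c(siteR@strand, siteD@strand),
    role = c("sgR", "sgD"),
    verdict = cls@competitive)
  verdict <- list(gap_bp = cls@gapBp, pams_facing = cls@pamsFacing,
                  competitive = cls@competitive,
                  sgd_repression_risk = cls@sgdRepressionRisk,
                  context = cls@context)
  if (!is.null(tsvPath))
    utils::write.table(rows, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath))
    writeLines(jsonlite::toJSON(verdict, auto_unbox = TRUE), jsonPath)
  invisible(verdict)
}
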