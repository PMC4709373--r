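# Dataset reader/writer with validation, configuration with documented
# defaults, and small export helpers.

.DATASET_COLS <- c("ID", "TIME", "DV", "AMT", "RATE", "WT", "OCC", "CMPL",
                   "EVID", "MDV")

.validateDataset <- function(x) {
  if (!is.data.frame(x)) stop("dataset must be a data.frame")
  missingCols <- setdiff(.DATASET_COLS, names(x))
  if (length(missingCols))
    stop("missing mandatory column(s): ", paste(missingCols, collapse = ", "))
  for (id in unique(x$ID)) {
    rows <- which(x$ID == id)
    tt <- x$TIME[rows]
    bad <- which(diff(tt) < 0)
    if (length(bad))
      stop(sprintf("TIME decreases within ID %s at row %d", as.character(id),
                   rows[bad[1] + 1L]))
    cmpl <- unique(x$CMPL[rows])
    if (length(cmpl) > 1L)
      stop(sprintf("CMPL not constant within ID %s (rows %d..%d)",
                   as.character(id), rows[1], rows[length(rows)]))
  }
  orphanDv <- which(x$MDV == 1 & !is.na(x$DV))
  if (length(orphanDv))
    stop(sprintf("DV present although MDV = 1 at row %d", orphanDv[1]))
  noDv <- which(x$MDV == 0 & is.na(x$DV))
  if (length(noDv))
    stop(sprintf("DV missing although MDV = 0 at row %d", noDv[1]))
  invisible(TRUE)
}

#' Read and validate a longitudinal ferritin dataset
#'
#' The dataset layout follows the usual nonlinear mixed-effects convention:
#' columns ID, TIME (h), DV (ferritin ug/L; empty when MDV = 1), AMT (daily
#' dose, mg, on EVID = 1 rows), RATE (mg/h), WT (kg), OCC (occasion index),
#' CMPL (adherence proxy, constant within subject), EVID, MDV. TIME must be
#' non-decreasing within subject. Validation errors name the offending row.
#'
#' @param path CSV file path
#' @param timeUnit unit of the TIME column in the file: \code{"hours"}
#'   (default) or \code{"days"} (converted on read)
#' @return validated data.frame
#' @export
readDataset <- function(path, timeUnit = c("hours", "days")) {
  timeUnit <- match.arg(timeUnit)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (timeUnit == "days" && "TIME" %in% names(x)) x$TIME <- x$TIME * 24
  .validateDataset(x)
  x
}

#' @describeIn readDataset write a dataset (round-trips with the reader)
#' @param x dataset data.frame
#' @export
writeDataset <- function(x, path) {
  .validateDataset(x)
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' All model defaults in one nested list: the literature adult PK parameters,
#' the fixed disease turnover constants (with their \code{fixed} flags), the
#' drug slope and variance components, and the scenario-grid settings.
#'
#' @return nested list
#' @export
defaultConfig <- function() {
  list(
    pk = list(cl = 19.3, q = 17.6, v1 = 77.4, v2 = 238.0, refWeight = 70),
    disease = list(kin = 2e-4, kout = 4.5e-6, scl = 0.383, shp = 2.6e-4,
                   thetaScl = 0.845, thetaShp = 1.29, ferritinMed = 2260,
                   fixed = c("kin", "kout", "scl", "shp")),
    drug = list(slope = 4.81),
    estimation = list(omegaIIV = 0.082, omegaIOV = 0.252, sigma = 0.173,
                      occasionYears = 1,
                      estimate = c("slope", "omegaIIV", "sigma")),
    scenario = list(doses = c(30, 45, 60), weights = seq(15, 75, by = 10),
                    baselines = seq(3000, 12000, by = 1000),
                    fractions = seq(0.1, 0.9, by = 0.1), nSeeds = 20,
                    weight = 45, dosePerKg = 45, threshold = 2500,
                    capYears = 5),
    cohort = list(nSubjects = 27, dosePerKg = 40),
    seed = 1)
}

.mergeConfig <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a mapping")
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

.checkConfig <- function(cfg) {
  est <- cfg$estimation
  if (est$omegaIIV < 0 || est$omegaIOV < 0)
    stop("random-effect variances must be >= 0")
  if (est$sigma <= 0) stop("sigma must be > 0")
  numScalar <- c(cfg$pk[c("cl", "q", "v1", "v2", "refWeight")],
                 cfg$disease[c("kin", "kout", "scl", "shp")])
  if (any(!vapply(numScalar, is.numeric, logical(1))))
    stop("PK and disease parameters must be numeric")
  cfg
}

#' Load a YAML/JSON configuration over the documented defaults
#'
#' Unknown keys are rejected with the offending path; values not given keep
#' their defaults (with an empty or missing file the pure defaults are
#' returned).
#'
#' @param path YAML (or JSON, which YAML subsumes) file; \code{NULL} for pure
#'   defaults
#' @return validated nested configuration list
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .mergeConfig(cfg, user)
  }
  .checkConfig(cfg)
}

#' @describeIn loadConfig build a \code{\link{pkParameters}} from a config
#' @param cfg configuration list
#' @export
configPK <- function(cfg) {
  with(cfg$pk, pkParameters(cl, q, v1, v2, refWeight))
}

#' @describeIn loadConfig build a \code{\link{diseaseParameters}} from a
#'   config
#' @export
configDisease <- function(cfg) {
  with(cfg$disease, diseaseParameters(kin, kout, scl, shp, thetaScl,
                                      thetaShp, ferritinMed))
}

#' @describeIn loadConfig build a \code{\link{populationModel}} from a config
#' @export
configPopulation <- function(cfg) {
  populationModel(pk = configPK(cfg), disease = configDisease(cfg),
                  slope = cfg$drug$slope,
                  omegaIIV = cfg$estimation$omegaIIV,
                  omegaIOV = cfg$estimation$omegaIOV,
                  sigma = abs(cfg$estimation$sigma),
                  occasionYears = cfg$estimation$occasionYears)
}

#' Export a simulated trajectory as CSV
#'
#' @param traj result of \code{\link{simulateFerritin}}
#' @param path output CSV path
#' @export
writeTrajectory <- function(traj, path) {
  write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
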