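#' Read a long-format laboratory CSV
#'
#' Expected columns: patient_id, analyte, date (ISO-8601), value. Every
#' analyte must come from [analyteVocabulary()]; an unknown name is
#' rejected with the offending row number.
#'
#' @param path CSV path.
#' @return data.frame with a Date-typed \code{date} column.
#' @export
readLabs <- function(path) {
  labs <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "analyte", "date", "value")
  miss <- setdiff(need, names(labs))
  if (length(miss))
    stop("labs CSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!labs$analyte %in% analyteVocabulary())
  if (length(bad))
    stop(sprintf("unknown analyte '%s' in %s row %d",
                 labs$analyte[bad[1]], path, bad[1]))
  labs$date <- as.Date(labs$date)
  if (anyNA(labs$date)) stop("unparseable date in ", path)
  if (!is.numeric(labs$value) || anyNA(labs$value))
    stop("non-numeric or missing lab values in ", path)
  labs
}

#' Read a per-patient baseline CSV
#' @param path CSV path; must contain a unique \code{patient_id} column.
#' @return data.frame.
#' @export
readBaseline <- function(path) {
  b <- read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(b)) stop("baseline CSV lacks 'patient_id'")
  if (anyDuplicated(b$patient_id))
    stop("duplicate patient ids in ", path)
  b
}

#' Read an outcomes CSV (patient_id, time_days, event)
#' @param path CSV path.
#' @return data.frame.
#' @export
readOutcomes <- function(path) {
  o <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event")
  miss <- setdiff(need, names(o))
  if (length(miss))
    stop("outcomes CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(o$event %in% c(0, 1))) stop("event must be 0/1 in ", path)
  o
}

#' Write a synthetic cohort to CSV files
#'
#' Writes labs.csv (long format, ISO-8601 dates), baseline.csv,
#' outcomes.csv and truth.csv into a directory.
#'
#' @param cohort a [DiabetesCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "DiabetesCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("labs.csv", "baseline.csv", "outcomes.csv",
                            "truth.csv"))
  labs <- cohort@labs
  labs$date <- format(labs$date, "%Y-%m-%d")
  write.csv(labs, paths[1], row.names = FALSE)
  write.csv(cohort@baseline, paths[2], row.names = FALSE)
  write.csv(cohort@outcomes, paths[3], row.names = FALSE)
  write.csv(cohort@truth, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Write engineered features (values + missing mask) as CSV
#'
#' @param features a [ClinicalFeatures-class].
#' @param path values CSV path; the logical mask goes to a sibling file
#'   with suffix \code{_mask.csv}.
#' @return invisibly, the two paths.
#' @export
writeFeatures <- function(features, path) {
  stopifnot(is(features, "ClinicalFeatures"))
  v <- featureMatrix(features)
  m <- missingMask(features)
  maskPath <- sub("\\.csv$", "_mask.csv", path)
  write.csv(data.frame(patient_id = rownames(v), v, check.names = FALSE),
            path, row.names = FALSE)
  write.csv(data.frame(patient_id = rownames(m), m, check.names = FALSE),
            maskPath, row.names = FALSE)
  invisible(c(path, maskPath))
}

# recursive node -> plain list (JSON-safe)
.nodeToList <- function(node) {
  if (node$leaf)
    return(list(leaf = TRUE, id = node$id, n = node$n,
                events = node$events, depth = node$depth))
  list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
       depth = node$depth, left = .nodeToList(node$left),
       right = .nodeToList(node$right))
}

.nodeFromList <- function(lst) {
  if (isTRUE(lst$leaf))
    return(list(leaf = TRUE, id = as.integer(lst$id),
                n = as.integer(lst$n), events = as.integer(lst$events),
                depth = as.integer(lst$depth)))
  list(leaf = FALSE, feature = as.integer(lst$feature),
       threshold = as.numeric(lst$threshold),
       depth = as.integer(lst$depth),
       left = .nodeFromList(lst$left), right = .nodeFromList(lst$right))
}

#' Persist a fitted forest as JSON
#'
#' Serializes the trees (split structure and leaf cumulative-hazard
#' arrays), in-bag indices, weights, regularization strength and the
#' global event-time grid, so a model can be inspected or reloaded
#' without refitting.
#'
#' @param forest a [SurvivalForest-class].
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @seealso [readForestJSON()]
#' @export
writeForestJSON <- function(forest, path) {
  stopifnot(is(forest, "SurvivalForest"))
  obj <- list(
    weights = forest@weights, lambdaReg = forest@lambdaReg,
    timeGrid = forest@timeGrid, featureNames = forest@featureNames,
    params = forest@params,
    inbag = forest@inbag,
    trees = lapply(forest@trees, function(tr) list(
      root = .nodeToList(tr@root), timeGrid = tr@timeGrid,
      leafHazard = tr@leafHazard, leafN = tr@leafN,
      leafEvents = tr@leafEvents, params = tr@params)))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Reload a forest persisted by [writeForestJSON()]
#' @param path JSON path.
#' @return a [SurvivalForest-class].
#' @export
readForestJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  trees <- lapply(obj$trees, function(tr) {
    lh <- tr$leafHazard
    if (is.null(dim(lh)))
      lh <- matrix(as.numeric(lh), nrow = length(tr$leafN))
    new("SurvivalTree", root = .nodeFromList(tr$root),
        timeGrid = as.numeric(tr$timeGrid), leafHazard = lh,
        leafN = as.integer(tr$leafN),
        leafEvents = as.integer(tr$leafEvents),
        featureNames = as.character(obj$featureNames), params = tr$params)
  })
  inbag <- obj$inbag
  if (is.matrix(inbag))
    inbag <- lapply(seq_len(nrow(inbag)), function(i) inbag[i, ])
  new("SurvivalForest", trees = trees,
      inbag = lapply(inbag, as.integer),
      weights = as.numeric(obj$weights),
      lambdaReg = as.numeric(obj$lambdaReg %||% NA_real_),
      timeGrid = as.numeric(obj$timeGrid),
      featureNames = as.character(obj$featureNames), params = obj$params)
}
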