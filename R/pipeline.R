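#' Run the full analysis pipeline
#'
#' Ties the stages together: obtain a cohort (simulated, or read from
#' labs/baseline/outcomes CSVs), engineer the per-patient features, pad
#' missing values with -1, fit the regularized and weighted forest,
#' produce importance rankings and main-tree decision rules, run the
#' cross-validated model comparison, and write every artifact plus a run
#' manifest into the output directory. Idempotent for a fixed
#' configuration: re-running writes byte-identical numeric outputs.
#'
#' @param config a named list, or the path of a YAML/JSON file holding
#'   one. Recognized entries: \code{seed} (mandatory), \code{outputDir};
#'   either \code{simulate} (a list of [cohortSpec()] arguments) or
#'   \code{labs}/\code{baseline}/\code{outcomes} CSV paths;
#'   \code{windowStart}/\code{windowEnd} (ISO dates); \code{forest}
#'   (list: nTrees, mtry, minLeafEvents, maxDepth, nSplitCandidates);
#'   \code{lambdaGrid}; \code{folds}; \code{horizon};
#'   \code{topKRules}; \code{evaluate} (logical, default TRUE);
#'   \code{leakFreeHypoglycemia}; \code{ipcw}.
#' @return invisibly, a list with the fitted model, features, importance
#'   table, rules, evaluation report and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set a 'seed'")
  seed <- as.integer(config$seed)
  outDir <- config$outputDir %||% "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  window <- NULL
  if (!is.null(config$windowStart))
    window <- as.Date(c(config$windowStart, config$windowEnd))

  if (!is.null(config$simulate)) {
    spec <- do.call(cohortSpec,
                    c(config$simulate,
                      if (is.null(config$simulate$seed)) list(seed = seed)))
    cohort <- simulateCohort(spec)
    writeCohort(cohort, file.path(outDir, "cohort"))
    labs <- cohort@labs; baseline <- cohort@baseline
    outcomes <- cohort@outcomes
    if (is.null(window)) {
      bd <- as.Date(spec$baselineDate)
      window <- c(bd - round(spec$lookbackYears * 365.25), bd)
    }
  } else {
    labs <- readLabs(config$labs)
    baseline <- readBaseline(config$baseline)
    outcomes <- readOutcomes(config$outcomes)
    if (is.null(window)) window <- range(labs$date)
  }

  features <- buildFeatureMatrix(
    labs, baseline = baseline, window = window, outcomes = outcomes,
    leakFreeHypoglycemia = config$leakFreeHypoglycemia %||% TRUE)
  padded <- padMissing(features)
  writeFeatures(padded, file.path(outDir, "features.csv"))

  m <- match(outcomes$patient_id, rownames(featureMatrix(padded)))
  X <- featureMatrix(padded)[m, , drop = FALSE]
  time <- outcomes$time_days
  event <- outcomes$event

  fp <- config$forest %||% list()
  model <- fitRWRSF(time, event, X,
                    nTrees = fp$nTrees %||% 100L,
                    mtry = fp$mtry,
                    minLeafEvents = fp$minLeafEvents %||% 3L,
                    maxDepth = fp$maxDepth %||% 20L,
                    nSplitCandidates = fp$nSplitCandidates %||% 10L,
                    lambdaGrid = config$lambdaGrid %||%
                      c(0, 0.001, 0.01, 0.1, 1, 10),
                    nFolds = config$folds %||% 5L, seed = seed)
  writeForestJSON(model, file.path(outDir, "model.json"))

  imp <- importanceReport(model, time, event, X,
                          horizon = config$horizon,
                          seed = seed, ipcw = config$ipcw %||% FALSE)
  write.csv(imp, file.path(outDir, "importance.csv"), row.names = FALSE)

  rules <- extractRules(model, topK = config$topKRules %||% 5L,
                        time = time, event = event, X = X)
  writeLines(vapply(rules, format, ""), file.path(outDir, "rules.txt"))
  jsonlite::write_json(lapply(rules, unclass),
                       file.path(outDir, "rules.json"),
                       digits = I(17), auto_unbox = TRUE)

  report <- NULL
  if (config$evaluate %||% TRUE) {
    report <- crossValidate(time, event, X,
                            nFolds = config$folds %||% 5L, seed = seed,
                            nTrees = fp$nTrees %||% 100L,
                            mtry = fp$mtry,
                            minLeafEvents = fp$minLeafEvents %||% 3L,
                            maxDepth = fp$maxDepth %||% 20L,
                            nSplitCandidates = fp$nSplitCandidates %||% 10L,
                            lambdaGrid = config$lambdaGrid %||%
                              c(0, 0.001, 0.01, 0.1, 1, 10))
    write.csv(report, file.path(outDir, "evaluation.csv"),
              row.names = FALSE)
  }

  manifest <- list(config = config, seed = seed,
                   package = as.character(packageVersion("rwsurf")),
                   r_version = R.version.string,
                   lambdaReg = model@lambdaReg,
                   features = colnames(X), n = length(time),
                   events = sum(event))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(model = model, features = padded, importance = imp,
                 rules = rules, evaluation = report, outputDir = outDir))
}
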