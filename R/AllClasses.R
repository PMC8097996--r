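#' @import methods
#' @importFrom stats median quantile rnorm runif rbinom rnbinom sd setNames
#'   complete.cases
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Step cumulative hazard function
#'
#' A right-censored survival estimate stored as a step function: a strictly
#' increasing grid of event times and the non-decreasing cumulative hazard
#' attained at each. Evaluation follows the step convention
#' \eqn{H(t) = } value at the largest grid time \eqn{\le t}, with
#' \eqn{H(t) = 0} below the grid. An empty grid encodes the all-censored
#' case \eqn{H \equiv 0}.
#'
#' @slot times numeric, strictly increasing event-time grid (days).
#' @slot hazard numeric, non-decreasing cumulative hazard values, same
#'   length as \code{times}, all \eqn{\ge 0}.
#' @seealso [nelsonAalen()], [chfAt()]
#' @export
setClass("StepCHF", representation(times = "numeric", hazard = "numeric"))

setValidity("StepCHF", function(object) {
  t <- object@times; h <- object@hazard
  if (length(t) != length(h))
    return("'times' and 'hazard' must have equal length")
  if (length(t) && any(diff(t) <= 0))
    return("'times' must be strictly increasing")
  if (length(h) && (any(h < 0) || any(diff(h) < -1e-12)))
    return("'hazard' must be non-negative and non-decreasing")
  TRUE
})

#' Single survival decision tree
#'
#' A binary tree grown by log-rank splitting on right-censored records.
#' Internal nodes carry (feature, threshold) with the convention that
#' \code{x <= threshold} goes left; each leaf stores a Nelson-Aalen
#' cumulative hazard evaluated on the tree's shared event-time grid
#' (the distinct event times of the sample the tree was grown on).
#'
#' @slot root recursive node list (internal representation).
#' @slot timeGrid numeric, the tree's shared event-time grid.
#' @slot leafHazard numeric matrix, one row per leaf, cumulative hazard on
#'   \code{timeGrid}.
#' @slot leafN integer, members per leaf.
#' @slot leafEvents integer, events per leaf.
#' @slot featureNames character, training feature names.
#' @slot params list of growth hyperparameters.
#' @seealso [growTree()], [predictTreeCHF()]
#' @export
setClass("SurvivalTree", representation(
  root = "list", timeGrid = "numeric", leafHazard = "matrix",
  leafN = "integer", leafEvents = "integer",
  featureNames = "character", params = "list"))

setValidity("SurvivalTree", function(object) {
  if (nrow(object@leafHazard) < 1) return("tree must have at least one leaf")
  if (length(object@leafN) != nrow(object@leafHazard))
    return("leaf bookkeeping lengths disagree")
  if (ncol(object@leafHazard) != length(object@timeGrid))
    return("leaf hazard grid width must match timeGrid")
  if (length(object@timeGrid) &&
      any(apply(object@leafHazard, 1L, function(h) any(diff(h) < -1e-12))))
    return("leaf cumulative hazards must be non-decreasing")
  TRUE
})

#' Regularized and weighted random survival forest
#'
#' A bootstrap ensemble of survival trees combined with per-tree convex
#' weights. Immediately after [fitForest()] the weights are uniform
#' (\eqn{w_b = 1/B}, the plain random-survival-forest ensemble);
#' [learnWeights()] replaces them with the minimizer of an L2-regularized
#' discrete-hazard negative log-likelihood over the probability simplex.
#'
#' @slot trees list of [SurvivalTree-class] objects.
#' @slot inbag list of integer vectors: bootstrap row indices per tree.
#' @slot weights numeric, per-tree weights on the probability simplex.
#' @slot lambdaReg numeric, L2 regularization strength used to learn the
#'   weights (\code{NA} before weight learning).
#' @slot timeGrid numeric, global grid = distinct event times of the
#'   training data.
#' @slot featureNames character.
#' @slot params list: hyperparameters and the training seed.
#' @seealso [fitForest()], [fitRWRSF()], [predictRisk()]
#' @export
setClass("SurvivalForest", representation(
  trees = "list", inbag = "list", weights = "numeric",
  lambdaReg = "numeric", timeGrid = "numeric",
  featureNames = "character", params = "list"))

setValidity("SurvivalForest", function(object) {
  B <- length(object@trees)
  if (B < 1) return("forest must contain at least one tree")
  if (length(object@inbag) != B) return("one in-bag index set per tree required")
  w <- object@weights
  if (length(w) != B) return("one weight per tree required")
  if (any(w < -1e-8)) return("tree weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) return("tree weights must sum to 1")
  TRUE
})

#' Synthetic diabetic cohort
#'
#' Longitudinal laboratory series, per-patient baseline covariates and
#' right-censored survival outcomes generated by [simulateCohort()], with
#' the latent ground truth (per-patient analyte means, within-patient
#' volatilities and the true linear predictor) retained for
#' parameter-recovery testing.
#'
#' @slot labs data.frame: patient_id, analyte, date (Date), value.
#' @slot baseline data.frame: patient_id, age, sex, drug flags.
#' @slot outcomes data.frame: patient_id, time_days, event.
#' @slot truth data.frame of latent per-patient values.
#' @slot spec the generating specification (list from [cohortSpec()]).
#' @export
setClass("DiabetesCohort", representation(
  labs = "data.frame", baseline = "data.frame",
  outcomes = "data.frame", truth = "data.frame", spec = "list"))

setValidity("DiabetesCohort", function(object) {
  if (!all(object@outcomes$patient_id %in% object@baseline$patient_id))
    return("every patient in outcomes must appear in baseline")
  if (!all(object@outcomes$event %in% c(0, 1)))
    return("event indicator must be 0/1")
  if (any(object@outcomes$time_days < 0))
    return("time_days must be non-negative")
  horizon <- object@spec$followupYears
  if (!is.null(horizon) &&
      any(object@outcomes$time_days > horizon * 365.25 + 1e-9))
    return("time_days must not exceed the follow-up horizon")
  TRUE
})

#' Per-patient engineered clinical features
#'
#' A \linkS4class{SummarizedExperiment} with features as rows and patients
#' as columns, carrying two assays: \code{values} (numeric, \code{NA} where
#' missing) and \code{missing} (logical mask). Survival outcomes, when
#' known, live in \code{colData} (\code{time_days}, \code{event}).
#' [padMissing()] replaces \code{NA} values by \eqn{-1} while retaining the
#' mask for diagnostics.
#'
#' @seealso [buildFeatureMatrix()], [featureMatrix()], [missingMask()]
#' @export
#' @import SummarizedExperiment
setClass("ClinicalFeatures", contains = "SummarizedExperiment")

setValidity("ClinicalFeatures", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("values", "missing") %in% an))
    return("assays 'values' and 'missing' are required")
  if (anyDuplicated(rownames(object)))
    return("feature names must be unique")
  if (!is.logical(SummarizedExperiment::assay(object, "missing")))
    return("'missing' assay must be logical")
  TRUE
})

#' Cox proportional-hazards baseline
#'
#' Comparator model for the weighted forest: a Cox fit with Breslow tie
#' handling (Efron available behind a flag), its Breslow baseline
#' cumulative hazard, and convergence diagnostics. The risk score used in
#' evaluation is the linear predictor.
#'
#' @slot coefficients named numeric.
#' @slot baselineHazard data.frame with columns time, hazard.
#' @slot converged logical.
#' @slot center named numeric, feature means used for the linear predictor.
#' @slot fit the underlying \code{survival::coxph} object.
#' @seealso [fitCox()], [predictCoxRisk()]
#' @export
setClass("CoxBaseline", representation(
  coefficients = "numeric", baselineHazard = "data.frame",
  converged = "logical", center = "numeric", fit = "ANY"))
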