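#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setGeneric("missingMask", function(x, ...) standardGeneric("missingMask"))

#' @rdname forest-accessors
#' @export
setGeneric("treeWeights", function(x) standardGeneric("treeWeights"))

#' @rdname forest-accessors
#' @export
setGeneric("lambdaReg", function(x) standardGeneric("lambdaReg"))

#' @rdname forest-accessors
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname forest-accessors
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' Extract feature values and missingness
#'
#' \code{featureMatrix} returns the patients-by-features numeric matrix of a
#' [ClinicalFeatures-class] object (the transpose of its \code{values}
#' assay); \code{missingMask} returns the matching logical mask, which is
#' preserved across [padMissing()].
#'
#' @param x a \code{ClinicalFeatures} object.
#' @param ... unused.
#' @return numeric (or logical) matrix, patients in rows.
#' @name featureMatrix
#' @aliases featureMatrix,ClinicalFeatures-method
#'   missingMask,ClinicalFeatures-method
NULL

setMethod("featureMatrix", "ClinicalFeatures", function(x, ...)
  t(SummarizedExperiment::assay(x, "values")))

setMethod("missingMask", "ClinicalFeatures", function(x, ...)
  t(SummarizedExperiment::assay(x, "missing")))

#' Forest accessors
#'
#' @param x a [SurvivalForest-class].
#' @return \code{treeWeights}: numeric simplex weights; \code{lambdaReg}:
#'   the L2 strength used for weight learning (\code{NA} if weights are
#'   still uniform from fitting); \code{timeGrid}: the global event-time
#'   grid; \code{nTrees}: number of trees.
#' @name forest-accessors
#' @aliases treeWeights,SurvivalForest-method lambdaReg,SurvivalForest-method
#'   timeGrid,SurvivalForest-method nTrees,SurvivalForest-method
NULL

setMethod("treeWeights", "SurvivalForest", function(x) x@weights)
setMethod("lambdaReg", "SurvivalForest", function(x) x@lambdaReg)
setMethod("timeGrid", "SurvivalForest", function(x) x@timeGrid)
setMethod("nTrees", "SurvivalForest", function(x) length(x@trees))

setMethod("show", "StepCHF", function(object) {
  k <- length(object@times)
  cat("StepCHF with", k, "event time(s)\n")
  if (k) cat("  H(", object@times[k], ") = ",
             format(object@hazard[k], digits = 4), "\n", sep = "")
})

setMethod("show", "SurvivalTree", function(object) {
  cat("SurvivalTree:", nrow(object@leafHazard), "leaves,",
      length(object@timeGrid), "grid times, depth",
      object@params$depth %||% NA, "\n")
})

setMethod("show", "SurvivalForest", function(object) {
  B <- length(object@trees)
  w <- object@weights
  cat("SurvivalForest with", B, "trees\n")
  cat("  weights:", if (max(w) - min(w) < 1e-12) "uniform"
      else sprintf("learned (max %.3f, min %.3f)", max(w), min(w)), "\n")
  cat("  lambdaReg:", object@lambdaReg, "\n")
  cat("  features:", length(object@featureNames), "\n")
})

setMethod("show", "DiabetesCohort", function(object) {
  cat("DiabetesCohort:", nrow(object@baseline), "patients,",
      nrow(object@labs), "lab measurements,",
      sum(object@outcomes$event), "events\n")
})

setMethod("show", "CoxBaseline", function(object) {
  cat("CoxBaseline (Breslow ties):", length(object@coefficients),
      "coefficients;", if (object@converged) "converged" else
      "DID NOT CONVERGE", "\n")
})
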