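#' Harrell's concordance index
#'
#' Discrimination of a risk score on right-censored data: among comparable
#' pairs \eqn{(i, j)} with \eqn{t_i < t_j} and \eqn{\delta_i = 1}, the
#' fraction in which the earlier-failing subject has the higher risk,
#' ties in risk crediting one half. A generalization of the area under
#' the ROC curve that handles right censoring.
#'
#' @param risk numeric risk scores (higher = riskier).
#' @param time,event right-censored outcome.
#' @return number in \[0, 1\]; \code{NA} (with a message) when no pair is
#'   comparable.
#' @export
harrellCIndex <- function(risk, time, event) {
  .checkSurvivalData(time, event)
  stopifnot(length(risk) == length(time), all(is.finite(risk)))
  n <- length(risk)
  conc <- 0; ties <- 0; comp <- 0
  ev <- which(event == 1)
  if (length(ev)) {
    # pairs (i, j): i an event, t_i < t_j
    for (i in ev) {
      later <- time > time[i]
      m <- sum(later)
      if (!m) next
      comp <- comp + m
      conc <- conc + sum(risk[i] > risk[later])
      ties <- ties + sum(risk[i] == risk[later])
    }
  }
  if (comp == 0) {
    message("no comparable pairs; concordance is undefined")
    return(NA_real_)
  }
  (conc + 0.5 * ties) / comp
}

#' Precision, recall and AUC of a risk score against a binary status
#'
#' AUC is the rank-based probability that an event case outranks a
#' non-event case (ties credited one half, the Wilcoxon form). Precision
#' and recall are computed at an explicit operating point: by default a
#' subject is predicted positive when its risk is at or above the cohort
#' median risk.
#'
#' @param risk numeric risk scores.
#' @param status 0/1 outcome labels (event observed during follow-up).
#' @param threshold predicted-positive cut-point on the risk scale;
#'   default \code{median(risk)}.
#' @return named list: precision, recall, auc (auc is \code{NA} when only
#'   one class is present).
#' @export
binaryMetrics <- function(risk, status, threshold = NULL) {
  stopifnot(length(risk) == length(status), all(status %in% c(0, 1)))
  threshold <- threshold %||% median(risk)
  pos <- risk >= threshold
  tp <- sum(pos & status == 1)
  precision <- if (sum(pos)) tp / sum(pos) else NA_real_
  recall <- if (sum(status == 1)) tp / sum(status == 1) else NA_real_
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  auc <- if (n1 && n0) {
    r <- rank(risk)                     # midranks handle ties (0.5 credit)
    (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  list(precision = precision, recall = recall, auc = auc)
}

#' Fit the Cox proportional-hazards baseline
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling (Efron
#' behind the \code{ties} flag) via \code{survival::coxph}
#' (Newton-Raphson, tolerance 1e-8, up to 100 iterations), returning the
#' coefficients, the Breslow baseline cumulative hazard and convergence
#' diagnostics. The evaluation risk score is the linear predictor.
#'
#' @param time,event right-censored outcome.
#' @param X numeric feature matrix; constant features are rejected.
#' @param ties "breslow" (default) or "efron".
#' @return a [CoxBaseline-class]. Non-convergence is flagged with a
#'   warning; the last iterate's coefficients are returned.
#' @export
fitCox <- function(time, event, X, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  .checkSurvivalData(time, event, X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  if (any(const))
    stop("constant feature(s): ", paste(colnames(X)[const], collapse = ", "))
  if (length(time) <= ncol(X))
    stop("need more records than features for the Cox baseline")
  df <- data.frame(X, check.names = FALSE)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ ., data = df,
                    ties = ties,
                    control = survival::coxph.control(eps = 1e-8,
                                                      iter.max = 100L)),
    warning = function(w) {
      if (grepl("converge|infinite|beta", conditionMessage(w))) {
        converged <<- FALSE
        warning("Cox baseline did not converge cleanly: ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  bh <- survival::basehaz(fit, centered = FALSE)
  new("CoxBaseline", coefficients = stats::coef(fit),
      baselineHazard = data.frame(time = bh$time, hazard = bh$hazard),
      converged = converged,
      center = colMeans(X), fit = fit)
}

#' Cox risk score (linear predictor)
#'
#' @param cox a [CoxBaseline-class].
#' @param X feature matrix.
#' @return numeric linear predictor per row.
#' @export
predictCoxRisk <- function(cox, X) {
  stopifnot(is(cox, "CoxBaseline"))
  X <- .checkFeatures(X, names(cox@coefficients))
  as.vector(X %*% cox@coefficients)
}

#' Five-fold cross-validated model comparison
#'
#' The model-comparison protocol: records are split into event-stratified
#' folds; on each fold's training part the bootstrap ensemble is grown
#' once and evaluated twice - with learned, L2-regularized weights
#' (rwrsf, its regularization strength tuned by inner cross-validation on
#' the fold-training data) and with uniform weights (rsf) - alongside a
#' Cox baseline. Held-out metrics per fold: Harrell's C-index on the
#' right-censored outcome, and precision/recall/AUC against the binary
#' event-during-follow-up status at the median-risk operating point.
#'
#' @param time,event,X the cohort records (features -1-padded).
#' @param models subset of \code{c("rwrsf", "rsf", "cox")}.
#' @param nFolds folds (default 5).
#' @param seed fold and model seed; fixed seed gives identical folds.
#' @param nTrees,mtry,minLeafEvents,maxDepth,nSplitCandidates,lambdaGrid,
#'   innerFolds forest hyperparameters.
#' @param statusHorizon optional horizon (days) restricting the binary
#'   status to events by that time; default whole follow-up.
#' @return data.frame of class \code{EvaluationReport}: model, fold (or
#'   "mean"), c_index, auc, precision, recall, n, events.
#' @export
crossValidate <- function(time, event, X,
                          models = c("rwrsf", "rsf", "cox"),
                          nFolds = 5L, seed = 1L, nTrees = 100L,
                          mtry = NULL, minLeafEvents = 3L, maxDepth = 20L,
                          nSplitCandidates = 10L,
                          lambdaGrid = c(0, 0.001, 0.01, 0.1, 1, 10),
                          innerFolds = 5L, statusHorizon = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  .checkSurvivalData(time, event, X)
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(nFolds >= 2L)
  folds <- .stratifiedFolds(event, nFolds, seed = as.integer(seed))

  status <- if (is.null(statusHorizon)) event
            else as.integer(event == 1 & time <= statusHorizon)

  rows <- list()
  for (k in seq_len(nFolds)) {
    tr <- which(folds != k); te <- which(folds == k)
    noEvents <- sum(event[te]) == 0
    if (noEvents)
      warning("fold ", k, " has no events; its metrics are missing")
    risks <- list()
    if (any(c("rwrsf", "rsf") %in% models)) {
      forest <- fitForest(time[tr], event[tr], X[tr, , drop = FALSE],
                          nTrees = nTrees, mtry = mtry,
                          minLeafEvents = minLeafEvents,
                          maxDepth = maxDepth,
                          nSplitCandidates = nSplitCandidates,
                          seed = as.integer(seed) + k)
      if ("rsf" %in% models)
        risks$rsf <- predictRisk(forest, X[te, , drop = FALSE],
                                 weights = forest@weights)$mortality
      if ("rwrsf" %in% models) {
        lam <- selectLambda(forest, time[tr], event[tr],
                            X[tr, , drop = FALSE], lambdaGrid,
                            nFolds = innerFolds,
                            seed = as.integer(seed) + k)
        w <- learnWeights(forest, time[tr], event[tr],
                          X[tr, , drop = FALSE], lambdaReg = as.numeric(lam))
        risks$rwrsf <- predictRisk(forest, X[te, , drop = FALSE],
                                   weights = as.vector(w))$mortality
      }
    }
    if ("cox" %in% models) {
      keepCols <- apply(X[tr, , drop = FALSE], 2L,
                        function(v) length(unique(v)) > 1L)
      cox <- fitCox(time[tr], event[tr], X[tr, keepCols, drop = FALSE])
      risks$cox <- predictCoxRisk(cox, X[te, keepCols, drop = FALSE])
    }
    for (m in models) {
      if (noEvents) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, fold = as.character(k), c_index = NA_real_,
          auc = NA_real_, precision = NA_real_, recall = NA_real_,
          n = length(te), events = 0L, stringsAsFactors = FALSE)
        next
      }
      ci <- harrellCIndex(risks[[m]], time[te], event[te])
      bm <- binaryMetrics(risks[[m]], status[te])
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, fold = as.character(k), c_index = ci, auc = bm$auc,
        precision = bm$precision, recall = bm$recall,
        n = length(te), events = sum(event[te]), stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(models, function(m) {
    sub <- report[report$model == m, ]
    data.frame(model = m, fold = "mean",
               c_index = mean(sub$c_index, na.rm = TRUE),
               auc = mean(sub$auc, na.rm = TRUE),
               precision = mean(sub$precision, na.rm = TRUE),
               recall = mean(sub$recall, na.rm = TRUE),
               n = sum(sub$n), events = sum(sub$events),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(report, means)
  class(out) <- c("EvaluationReport", "data.frame")
  attr(out, "config") <- list(nFolds = nFolds, seed = seed,
                              nTrees = nTrees, lambdaGrid = lambdaGrid,
                              models = models)
  out
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("Model performance (", attr(x, "config")$nFolds,
      "-fold cross-validation)\n", sep = "")
  m <- x[x$fold == "mean", c("model", "precision", "recall", "auc",
                             "c_index")]
  rownames(m) <- NULL
  print(format(m, digits = 4), ...)
  invisible(x)
}
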