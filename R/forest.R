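#' Fit a bootstrap ensemble of survival trees
#'
#' Grows \code{nTrees} survival trees, each on an n-out-of-n bootstrap
#' sample of the records, recording the in-bag indices (out-of-bag sets
#' follow by complement). Each tree's event-time grid is the set of
#' distinct event times of its bootstrap sample; the forest's global grid
#' is the distinct event times of the full training data. Weights are
#' initialized uniform, \eqn{w_b = 1/B}: at this point the model is a
#' plain random survival forest. Deterministic for a fixed seed.
#'
#' @param time,event right-censored outcome (days, 0/1).
#' @param X numeric feature matrix (records x features), -1-padded.
#' @param nTrees number of trees (default 100).
#' @param mtry,minLeafEvents,maxDepth,nSplitCandidates passed to
#'   [growTree()].
#' @param seed integer seed.
#' @return a [SurvivalForest-class] with uniform weights and
#'   \code{lambdaReg = NA}.
#' @export
fitForest <- function(time, event, X, nTrees = 100L, mtry = NULL,
                      minLeafEvents = 3L, maxDepth = 20L,
                      nSplitCandidates = 10L, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  .checkSurvivalData(time, event, X)
  stopifnot(nTrees >= 1L)
  set.seed(as.integer(seed))
  n <- length(time)
  trees <- vector("list", nTrees)
  inbag <- vector("list", nTrees)
  for (b in seq_len(nTrees)) {
    idx <- sample.int(n, n, replace = TRUE)
    inbag[[b]] <- idx
    trees[[b]] <- growTree(time[idx], event[idx], X[idx, , drop = FALSE],
                           mtry = mtry, minLeafEvents = minLeafEvents,
                           maxDepth = maxDepth,
                           nSplitCandidates = nSplitCandidates)
  }
  new("SurvivalForest", trees = trees, inbag = inbag,
      weights = rep(1 / nTrees, nTrees), lambdaReg = NA_real_,
      timeGrid = sort(unique(time[event == 1])),
      featureNames = colnames(X) %||% paste0("x", seq_len(ncol(X))),
      params = list(nTrees = nTrees, mtry = mtry,
                    minLeafEvents = minLeafEvents, maxDepth = maxDepth,
                    nSplitCandidates = nSplitCandidates, seed = seed,
                    nRecords = n))
}

# per-tree leaf hazards resampled onto the forest's global grid
.leafHazardGlobal <- function(forest) {
  lapply(forest@trees, function(tr)
    .resampleHazard(tr@leafHazard, tr@timeGrid, forest@timeGrid))
}

# n x B matrix of leaf ids: record i routed through tree b
.routeForest <- function(forest, X) {
  matrix(vapply(forest@trees, function(tr) .routeTree(tr@root, X),
                integer(nrow(X))),
         nrow(X), length(forest@trees))
}

# per-record per-tree CHF value H_b(t_i | x_i) and grid increment
# Delta_b(t_i | x_i) at the grid time nearest <= t_i
.recordHazards <- function(forest, time, X) {
  grid <- forest@timeGrid
  k <- findInterval(time, grid)
  lhg <- .leafHazardGlobal(forest)
  ids <- .routeForest(forest, X)
  n <- length(time); B <- nTrees(forest)
  H <- matrix(0, n, B); D <- matrix(0, n, B)
  pos <- k > 0L
  for (b in seq_len(B)) {
    Lh <- cbind(0, lhg[[b]])
    H[pos, b] <- Lh[cbind(ids[pos, b], k[pos] + 1L)]
    D[pos, b] <- H[pos, b] - Lh[cbind(ids[pos, b], k[pos])]
  }
  list(H = H, Delta = D)
}

#' Predict ensemble risk
#'
#' The weighted ensemble cumulative hazard
#' \eqn{H_w(t|x) = \sum_b w_b H_b(t|x)} on the forest's global event-time
#' grid (a plain arithmetic mean of tree CHFs under uniform weights), the
#' survival curve \eqn{S(t) = e^{-H_w(t)}}, and the scalar mortality risk
#' score: the sum of the ensemble CHF over the grid times.
#'
#' @param forest a [SurvivalForest-class].
#' @param X feature vector or matrix of records to predict.
#' @param weights optional simplex weights overriding the forest's.
#' @return list with \code{times} (global grid), \code{chf} and
#'   \code{survival} (records x grid matrices), and \code{mortality}
#'   (numeric vector).
#' @export
predictRisk <- function(forest, X, weights = NULL) {
  stopifnot(is(forest, "SurvivalForest"))
  X <- .checkFeatures(X, forest@featureNames)
  w <- weights %||% forest@weights
  .checkSimplex(w)
  lhg <- .leafHazardGlobal(forest)
  ids <- .routeForest(forest, X)
  H <- matrix(0, nrow(X), length(forest@timeGrid))
  for (b in seq_len(nTrees(forest)))
    H <- H + w[b] * lhg[[b]][ids[, b], , drop = FALSE]
  list(times = forest@timeGrid, chf = H, survival = exp(-H),
       mortality = rowSums(H))
}

#' Discrete-hazard negative log-likelihood of ensemble weights
#'
#' The loss the tree weights are learned under. Per record \eqn{i} with
#' follow-up \eqn{t_i} and indicator \eqn{\delta_i}:
#' \deqn{-\delta_i \log(\Delta H_w(t_i|x_i) + \epsilon) + H_w(t_i|x_i)}
#' where \eqn{\Delta H_w(t_i|x_i)} is the weighted hazard increment at the
#' grid time nearest \eqn{\le t_i} and \eqn{\epsilon = 10^{-12}} floors
#' the logarithm; the value returned is the mean over records. Censored
#' records contribute only the cumulative-hazard (survivor) term.
#'
#' @param forest a fitted [SurvivalForest-class].
#' @param time,event records to score.
#' @param X their feature matrix.
#' @param weights simplex weights (tolerance 1e-8; off-simplex input is
#'   rejected).
#' @param eps log floor, default 1e-12.
#' @return mean negative log-likelihood (a number).
#' @export
ensembleNegLogLik <- function(forest, time, event, X,
                              weights = NULL, eps = 1e-12) {
  stopifnot(is(forest, "SurvivalForest"))
  X <- .checkFeatures(X, forest@featureNames)
  .checkSurvivalData(time, event, X)
  w <- weights %||% forest@weights
  .checkSimplex(w)
  rh <- .recordHazards(forest, time, X)
  .negLogLik(rh$Delta, rh$H, event, w, eps)
}

.negLogLik <- function(Delta, H, event, w, eps = 1e-12) {
  hw <- as.vector(H %*% w)
  dw <- as.vector(Delta %*% w)
  mean(-event * log(dw + eps) + hw)
}

.negLogLikGrad <- function(Delta, H, event, w, eps = 1e-12) {
  dw <- as.vector(Delta %*% w)
  (-as.vector(crossprod(Delta, event / (dw + eps))) + colSums(H)) /
    length(event)
}

# Cox partial-likelihood alternative loss on the mortality score
# (Breslow form): risk_i = (M w)_i with M the per-record per-tree
# mortality matrix.
.coxPartial <- function(M, time, event, w) {
  eta <- as.vector(M %*% w)
  ord <- order(time)
  r <- exp(eta[ord]); e <- event[ord]
  denom <- rev(cumsum(rev(r)))            # sum over at-risk (time >= t_i)
  -(sum(eta[ord][e == 1]) - sum(log(denom[e == 1]))) / max(sum(e), 1)
}

.coxPartialGrad <- function(M, time, event, w) {
  eta <- as.vector(M %*% w)
  ord <- order(time)
  r <- exp(eta[ord]); e <- event[ord]
  denom <- rev(cumsum(rev(r)))
  # P_i = r_i * sum_{events j with t_j <= t_i} 1/denom_j
  invd <- ifelse(e == 1, 1 / denom, 0)
  P <- r * cumsum(invd)
  g <- numeric(length(eta))
  g[ord] <- -(e - P)
  as.vector(crossprod(M, g)) / max(sum(event), 1)
}

#' Learn regularized tree weights
#'
#' Minimizes, over the probability simplex, the ensemble negative
#' log-likelihood plus an L2 penalty
#' \eqn{\lambda \sum_b w_b^2}, by projected gradient descent from the
#' uniform start: each iterate is a simplex projection of a gradient
#' step, accepted only under backtracking (so the penalized objective
#' never increases), stopping when the projected step is below
#' \code{tol = 1e-6} or after 500 iterations. Large \eqn{\lambda} drives
#' the weights to uniform (the penalty's simplex minimizer).
#'
#' @param forest a fitted [SurvivalForest-class].
#' @param time,event,X training records (by default weight learning uses
#'   the forest's own training data supplied here).
#' @param lambdaReg non-negative L2 strength.
#' @param loss \code{"discrete_hazard"} (default) or \code{"cox_partial"}
#'   (partial likelihood of the mortality score).
#' @param maxIter,tol optimizer controls.
#' @param eps log floor for the discrete-hazard loss.
#' @return simplex weight vector with attributes \code{objective} (the
#'   iterate trace) and \code{iterations}.
#' @export
learnWeights <- function(forest, time, event, X, lambdaReg,
                         loss = c("discrete_hazard", "cox_partial"),
                         maxIter = 500L, tol = 1e-6, eps = 1e-12) {
  stopifnot(is(forest, "SurvivalForest"), lambdaReg >= 0)
  loss <- match.arg(loss)
  X <- .checkFeatures(X, forest@featureNames)
  .checkSurvivalData(time, event, X)
  B <- nTrees(forest)
  if (loss == "discrete_hazard") {
    rh <- .recordHazards(forest, time, X)
    f <- function(w) .negLogLik(rh$Delta, rh$H, event, w, eps)
    g <- function(w) .negLogLikGrad(rh$Delta, rh$H, event, w, eps)
  } else {
    lhg <- .leafHazardGlobal(forest)
    ids <- .routeForest(forest, X)
    M <- vapply(seq_len(B),
                function(b) rowSums(lhg[[b]][ids[, b], , drop = FALSE]),
                numeric(length(time)))
    f <- function(w) .coxPartial(M, time, event, w)
    g <- function(w) .coxPartialGrad(M, time, event, w)
  }
  .projectedGradient(f, g, B, lambdaReg, maxIter, tol)
}

.projectedGradient <- function(f, g, B, lambda, maxIter, tol) {
  w <- rep(1 / B, B)
  pen <- function(w) lambda * sum(w^2)
  obj <- f(w) + pen(w)
  if (!is.finite(obj)) stop("non-finite loss at the uniform start")
  trace <- obj
  step <- 1
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    gr <- g(w) + 2 * lambda * w
    if (any(!is.finite(gr)))
      stop("non-finite gradient during weight optimization (iteration ",
           iter, ")")
    accepted <- FALSE
    s <- step
    for (bt in 1:40) {
      wNew <- projectSimplex(w - s * gr)
      objNew <- f(wNew) + pen(wNew)
      if (is.finite(objNew) && objNew <= obj + 1e-12) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) break
    moved <- sqrt(sum((wNew - w)^2))
    w <- wNew; obj <- objNew
    trace <- c(trace, obj)
    step <- min(s * 2, 1e3)             # gentle step recovery
    if (moved / max(s, 1e-300) < tol || moved < 1e-14) break
  }
  structure(w, objective = trace, iterations = iter)
}

#' Select the regularization strength by five-fold cross-validation
#'
#' For each candidate \eqn{\lambda}, tree weights are learned on four of
#' five folds of the supplied training records (the trees themselves stay
#' fixed) and the unpenalized negative log-likelihood is evaluated on the
#' held-out fold; the \eqn{\lambda} with the smallest mean held-out loss
#' wins, ties going to the larger (more regularized) value. A fold
#' without events still contributes its censoring terms, with a warning.
#'
#' @param forest a fitted [SurvivalForest-class].
#' @param time,event,X training records.
#' @param lambdaGrid non-empty numeric grid, default
#'   \code{c(0, 0.001, 0.01, 0.1, 1, 10)}.
#' @param nFolds folds (default 5).
#' @param seed fold-assignment seed.
#' @param loss passed to [learnWeights()].
#' @return the selected \eqn{\lambda}, with attribute \code{cvLoss}
#'   (mean held-out loss per grid value).
#' @export
selectLambda <- function(forest, time, event, X,
                         lambdaGrid = c(0, 0.001, 0.01, 0.1, 1, 10),
                         nFolds = 5L, seed = 1L,
                         loss = "discrete_hazard") {
  stopifnot(length(lambdaGrid) >= 1L)
  loss <- match.arg(loss, c("discrete_hazard", "cox_partial"))
  X <- .checkFeatures(X, forest@featureNames)
  if (length(lambdaGrid) == 1L)
    return(structure(lambdaGrid, cvLoss = NA_real_))
  B <- nTrees(forest)
  if (loss == "discrete_hazard") {
    rh <- .recordHazards(forest, time, X)
    lossFG <- function(idx) list(
      f = function(w) .negLogLik(rh$Delta[idx, , drop = FALSE],
                                 rh$H[idx, , drop = FALSE], event[idx], w),
      g = function(w) .negLogLikGrad(rh$Delta[idx, , drop = FALSE],
                                     rh$H[idx, , drop = FALSE], event[idx], w))
  } else {
    lhg <- .leafHazardGlobal(forest)
    ids <- .routeForest(forest, X)
    M <- vapply(seq_len(B),
                function(b) rowSums(lhg[[b]][ids[, b], , drop = FALSE]),
                numeric(length(time)))
    lossFG <- function(idx) list(
      f = function(w) .coxPartial(M[idx, , drop = FALSE],
                                  time[idx], event[idx], w),
      g = function(w) .coxPartialGrad(M[idx, , drop = FALSE],
                                      time[idx], event[idx], w))
  }
  set.seed(as.integer(seed))
  folds <- .stratifiedFolds(event, nFolds)
  cvLoss <- sapply(lambdaGrid, function(lam) {
    mean(vapply(seq_len(nFolds), function(k) {
      tr <- which(folds != k); te <- which(folds == k)
      if (sum(event[te]) == 0)
        warning("cross-validation fold ", k,
                " has no events; held-out loss uses censoring terms only")
      fg <- lossFG(tr)
      w <- .projectedGradient(fg$f, fg$g, B, lam, 500L, 1e-6)
      lossFG(te)$f(w)
    }, numeric(1)))
  })
  best <- min(cvLoss)
  structure(max(lambdaGrid[cvLoss <= best + 1e-12]),
            cvLoss = setNames(cvLoss, lambdaGrid))
}

#' Fit the regularized and weighted random survival forest
#'
#' The full pipeline of the method: grow the bootstrap ensemble
#' ([fitForest()]), choose the L2 regularization strength by five-fold
#' cross-validation on the training records ([selectLambda()]), then
#' learn the per-tree weights at the chosen strength ([learnWeights()]).
#'
#' @param time,event,X training records (features -1-padded).
#' @param nTrees,mtry,minLeafEvents,maxDepth,nSplitCandidates forest
#'   hyperparameters, see [fitForest()].
#' @param lambdaGrid candidate L2 strengths; a single value (or
#'   \code{lambdaReg}) skips the cross-validation.
#' @param lambdaReg optional fixed strength overriding the grid search.
#' @param nFolds inner cross-validation folds.
#' @param loss weight-learning loss, see [learnWeights()].
#' @param seed seed for bootstrap, tree growth and fold assignment.
#' @return a [SurvivalForest-class] with learned weights and
#'   \code{lambdaReg} set.
#' @examples
#' \donttest{
#' sc <- simulateCohort(cohortSpec(120, seed = 3))
#' fm <- padMissing(buildFeatureMatrix(sc))
#' fit <- fitRWRSF(sc@outcomes$time_days, sc@outcomes$event,
#'                 featureMatrix(fm), nTrees = 20, seed = 3)
#' fit
#' }
#' @export
fitRWRSF <- function(time, event, X, nTrees = 100L, mtry = NULL,
                     minLeafEvents = 3L, maxDepth = 20L,
                     nSplitCandidates = 10L,
                     lambdaGrid = c(0, 0.001, 0.01, 0.1, 1, 10),
                     lambdaReg = NULL, nFolds = 5L,
                     loss = "discrete_hazard", seed = 1L) {
  forest <- fitForest(time, event, X, nTrees = nTrees, mtry = mtry,
                      minLeafEvents = minLeafEvents, maxDepth = maxDepth,
                      nSplitCandidates = nSplitCandidates, seed = seed)
  lam <- if (!is.null(lambdaReg)) lambdaReg
         else selectLambda(forest, time, event, X, lambdaGrid,
                           nFolds = nFolds, seed = seed, loss = loss)
  w <- learnWeights(forest, time, event, X, lambdaReg = as.numeric(lam),
                    loss = loss)
  forest@weights <- as.vector(w)
  forest@lambdaReg <- as.numeric(lam)
  forest@params$loss <- loss
  forest@params$lambdaGrid <- if (is.null(lambdaReg)) lambdaGrid else NA
  validObject(forest)
  forest
}
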