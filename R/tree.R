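#' Nelson-Aalen cumulative hazard estimator
#'
#' Nonparametric estimate of the cumulative hazard of right-censored data:
#' at each distinct event time \eqn{t}, the increment is \eqn{d(t)/Y(t)}
#' (events over at-risk count, censorings at \eqn{t} counted as at risk),
#' cumulated over ordered event times. With no events the estimate is
#' identically zero on an empty grid.
#'
#' @param time non-negative follow-up times (days).
#' @param event 0/1 event indicator.
#' @return a [StepCHF-class].
#' @examples
#' H <- nelsonAalen(c(1, 2, 3), c(1, 1, 1))
#' chfAt(H, 3)  # 1/3 + 1/2 + 1 = 11/6
#' @export
nelsonAalen <- function(time, event) {
  .checkSurvivalData(time, event)
  if (length(time) < 1L) stop("at least one record is required")
  na <- .nelsonAalen(time, event)
  StepCHF(na$times, na$hazard)
}

# plain-vector core: list(times, hazard); sorted = TRUE skips the sort
.nelsonAalen <- function(time, event, sorted = FALSE) {
  if (!sorted) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]
  }
  if (!any(event == 1)) return(list(times = numeric(0), hazard = numeric(0)))
  evTimes <- unique(time[event == 1])
  # events per distinct event time
  d <- as.vector(rowsum(event, time)[match(evTimes, unique(time)), ])
  # at-risk: all records with time >= s; first occurrence index in sorted t
  Y <- length(time) - match(evTimes, time) + 1L
  list(times = evTimes, hazard = cumsum(d / Y))
}

#' Two-sample log-rank statistic
#'
#' Standardized absolute log-rank statistic |O - E| / sqrt(V) between two
#' groups of right-censored records; larger means better separation. A
#' degenerate variance (no events, or a group pattern with zero variance)
#' yields 0.
#'
#' @param timeLeft,eventLeft,timeRight,eventRight the two groups' times
#'   and 0/1 event indicators.
#' @return non-negative number.
#' @export
logrankStatistic <- function(timeLeft, eventLeft, timeRight, eventRight) {
  .checkSurvivalData(timeLeft, eventLeft)
  .checkSurvivalData(timeRight, eventRight)
  if (!length(timeLeft) || !length(timeRight))
    stop("both groups must be non-empty")
  time <- c(timeLeft, timeRight)
  event <- c(eventLeft, eventRight)
  memb <- c(rep(1, length(timeLeft)), rep(0, length(timeRight)))
  st <- .logrankSplitStats(time, event, memb, 0.5)
  st$stat[1L]
}

# Log-rank statistics for membership x <= threshold, all thresholds at
# once; counts aggregated by distinct time so the heavy ops are O(n K).
# Returns stat and child bookkeeping per threshold.
.logrankSplitStats <- function(time, event, x, thresholds, sorted = FALSE) {
  n <- length(time)
  K <- length(thresholds)
  if (!sorted) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; x <- x[ord]
  }
  M <- outer(x, thresholds, "<=")           # n x K membership (left side)
  storage.mode(M) <- "double"
  nLeft <- .colSums(M, n, K)
  totalEvents <- sum(event)
  if (totalEvents == 0)
    return(list(stat = rep(0, K), nLeft = nLeft, nRight = n - nLeft,
                eventsLeft = rep(0, K), eventsRight = rep(0, K)))
  newt <- !duplicated(time)
  grp <- cumsum(newt)                       # distinct-time group per row
  m <- grp[n]
  d <- as.vector(rowsum(event, grp))        # events per distinct time
  d1 <- rowsum(M * event, grp)              # ... in the left group (m x K)
  Mg <- rowsum(M, grp)
  # at-risk in the left group at each distinct time: nLeft minus members
  # seen strictly before it
  Y1 <- Mg
  for (k in seq_len(K)) {
    cs <- cumsum(Mg[, k])
    Y1[, k] <- nLeft[k] - c(0, cs[-m])
  }
  Y <- n - which(newt) + 1L
  keep <- d > 0
  d <- d[keep]; Y <- Y[keep]
  d1 <- d1[keep, , drop = FALSE]; Y1 <- Y1[keep, , drop = FALSE]
  p <- Y1 / Y
  O1 <- .colSums(d1, nrow(d1), K)
  E1 <- .colSums(d * p, nrow(p), K)
  vfac <- (Y - d) / pmax(Y - 1, 1)
  vfac[Y <= 1] <- 0
  V <- .colSums(d * p * (1 - p) * vfac, nrow(p), K)
  stat <- numeric(K)
  posV <- V > 0
  stat[posV] <- abs(O1[posV] - E1[posV]) / sqrt(V[posV])
  list(stat = stat, nLeft = nLeft, nRight = n - nLeft,
       eventsLeft = O1, eventsRight = totalEvents - O1)
}

#' Grow a survival decision tree
#'
#' Recursively partitions right-censored records by log-rank splitting: at
#' each node \code{mtry} features are sampled without replacement; for
#' each, up to \code{nSplitCandidates} thresholds are drawn from the
#' observed in-node values (all of them in exhaustive mode); the
#' admissible split (both children holding at least \code{minLeafEvents}
#' events) maximizing the standardized log-rank statistic is taken, with
#' \code{x <= threshold} routed left. Recursion stops at
#' \code{maxDepth}, when too few events remain, or when no admissible
#' split separates the node. Each leaf stores the Nelson-Aalen cumulative
#' hazard of its members, evaluated on the tree's shared grid (the
#' distinct event times of the training records). Uses the R RNG: seed
#' via \code{set.seed()} for reproducibility.
#'
#' @param time,event right-censored outcome.
#' @param X numeric feature matrix, records in rows (missing values are
#'   expected to be -1-padded; -1 routes like any number).
#' @param mtry features sampled per node; default \eqn{\lceil\sqrt p\rceil}.
#' @param minLeafEvents minimum events per leaf (default 3).
#' @param maxDepth maximum depth (root = 0; default 20).
#' @param nSplitCandidates thresholds drawn per feature (default 10).
#' @param exhaustive if \code{TRUE}, scan every observed threshold of every
#'   feature (\code{mtry} forced to all features' candidates still being
#'   sampled \code{mtry} at a time).
#' @return a [SurvivalTree-class].
#' @export
growTree <- function(time, event, X, mtry = NULL, minLeafEvents = 3L,
                     maxDepth = 20L, nSplitCandidates = 10L,
                     exhaustive = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  .checkSurvivalData(time, event, X)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  if (mtry > p) stop("'mtry' must not exceed the number of features")

  grid <- sort(unique(time[event == 1]))
  env <- new.env(parent = emptyenv())
  env$leaves <- list()

  makeLeaf <- function(idx, depth) {
    na <- .nelsonAalen(time[idx], event[idx], sorted = TRUE)
    id <- length(env$leaves) + 1L
    env$leaves[[id]] <- .stepEval(na$times, na$hazard, grid)
    list(leaf = TRUE, id = id, n = length(idx),
         events = sum(event[idx]), depth = depth)
  }

  # idx is kept sorted by time throughout the recursion
  build <- function(idx, depth) {
    ev <- sum(event[idx])
    if (depth >= maxDepth || ev < 2L * minLeafEvents || length(idx) < 2L)
      return(makeLeaf(idx, depth))
    feats <- sample.int(p, mtry)
    best <- list(stat = 0)
    for (j in feats) {
      xs <- unique(X[idx, j])
      if (length(xs) < 2L) next
      cand <- sort.int(xs)
      cand <- cand[-length(cand)]          # keep the right child non-empty
      if (!exhaustive && length(cand) > nSplitCandidates)
        cand <- sample(cand, nSplitCandidates)
      st <- .logrankSplitStats(time[idx], event[idx], X[idx, j], cand,
                               sorted = TRUE)
      ok <- st$eventsLeft >= minLeafEvents & st$eventsRight >= minLeafEvents
      if (!any(ok)) next
      k <- which(ok)[which.max(st$stat[ok])]
      if (st$stat[k] > best$stat)
        best <- list(stat = st$stat[k], feature = j, threshold = cand[k])
    }
    if (best$stat <= 0) return(makeLeaf(idx, depth))
    goLeft <- X[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         depth = depth, stat = best$stat,
         left = build(idx[goLeft], depth + 1L),
         right = build(idx[!goLeft], depth + 1L))
  }

  root <- build(order(time), 0L)
  leaves <- .collectLeaves(root)
  leafHazard <- do.call(rbind, env$leaves)
  if (is.null(leafHazard))
    leafHazard <- matrix(numeric(0), 1L, 0L)
  new("SurvivalTree", root = root, timeGrid = grid,
      leafHazard = leafHazard,
      leafN = vapply(leaves, function(l) as.integer(l$n), 1L),
      leafEvents = vapply(leaves, function(l) as.integer(l$events), 1L),
      featureNames = colnames(X) %||% paste0("x", seq_len(p)),
      params = list(mtry = mtry, minLeafEvents = minLeafEvents,
                    maxDepth = maxDepth,
                    nSplitCandidates = nSplitCandidates,
                    exhaustive = exhaustive, depth = .treeDepth(root)))
}

.collectLeaves <- function(node) {
  if (node$leaf) return(list(node))
  out <- c(.collectLeaves(node$left), .collectLeaves(node$right))
  out[order(vapply(out, function(l) l$id, 1L))]
}

.treeDepth <- function(node) {
  if (node$leaf) return(node$depth)
  max(.treeDepth(node$left), .treeDepth(node$right))
}

# vectorized routing: leaf id per row of X
.routeTree <- function(root, X) {
  out <- integer(nrow(X))
  recur <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$leaf) { out[idx] <<- node$id; return(invisible()) }
    goLeft <- X[idx, node$feature] <= node$threshold
    recur(node$left, idx[goLeft])
    recur(node$right, idx[!goLeft])
  }
  recur(root, seq_len(nrow(X)))
  out
}

#' Predict a tree's cumulative hazard for a feature vector
#'
#' Routes the feature vector through the tree's splits (ties at a
#' threshold go left, the \code{<=} convention; -1-padded values route
#' like any number) and returns the reached leaf's Nelson-Aalen cumulative
#' hazard on the tree's shared event-time grid.
#'
#' @param tree a [SurvivalTree-class].
#' @param x numeric feature vector (or matrix of rows to predict).
#' @return a [StepCHF-class] for a single vector; a list of them for a
#'   matrix.
#' @export
predictTreeCHF <- function(tree, x) {
  stopifnot(is(tree, "SurvivalTree"))
  single <- is.null(dim(x))
  X <- .checkFeatures(x, tree@featureNames)
  ids <- .routeTree(tree@root, X)
  out <- lapply(ids, function(id)
    StepCHF(tree@timeGrid, tree@leafHazard[id, ]))
  if (single) out[[1L]] else out
}
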