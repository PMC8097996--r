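`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean projection onto the probability simplex
#'
#' Projects a numeric vector onto \eqn{\{w : w_b \ge 0, \sum_b w_b = 1\}}
#' (Held-Wolfe-Crowder / Duchi algorithm). Used by the projected-gradient
#' weight learner.
#'
#' @param v numeric vector.
#' @return numeric vector of the same length on the simplex.
#' @export
projectSimplex <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 1L, all(is.finite(v)))
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# stratified fold assignment: within each event stratum, shuffled indices
# are dealt round-robin so every fold gets its share of events
.stratifiedFolds <- function(event, nFolds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

.checkSimplex <- function(w, tol = 1e-8) {
  if (any(!is.finite(w)) || any(w < -tol) || abs(sum(w) - 1) > tol)
    stop("'weights' must lie on the probability simplex (non-negative, sum 1)")
  invisible(TRUE)
}

.checkFeatures <- function(X, featureNames) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (ncol(X) != length(featureNames))
    stop(sprintf("feature vector length %d does not match training length %d",
                 ncol(X), length(featureNames)))
  storage.mode(X) <- "double"
  X
}

.checkSurvivalData <- function(time, event, X = NULL) {
  stopifnot(is.numeric(time), all(is.finite(time)), all(time >= 0))
  if (!all(event %in% c(0, 1))) stop("'event' must be a 0/1 indicator")
  if (length(time) != length(event))
    stop("'time' and 'event' must have equal length")
  if (!is.null(X) && nrow(X) != length(time))
    stop("feature matrix rows must match the number of records")
  invisible(TRUE)
}
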