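#' Permutation variable importance on out-of-bag data
#'
#' Importance of a feature is the increase in out-of-bag squared-loss
#' prediction error when its values are permuted across records: larger
#' values indicate higher predictive strength, zero or negative values a
#' non-predictive variable. The error is a fixed-horizon squared loss
#' between the predicted event probability by the horizon,
#' \eqn{1 - S_w(h|x)}, and the observed status at the horizon, restricted
#' to records whose status is determinable (event on or before the
#' horizon: status 1; followed past the horizon: status 0; censored
#' earlier: excluded). Optionally the error terms are inverse-probability-
#' of-censoring weighted instead of restricted. Each record is predicted
#' only by the trees for which it is out-of-bag, with the forest weights
#' renormalized over those trees; the same permutation (fixed seed) is
#' applied per feature, so results are reproducible.
#'
#' @param forest a fitted [SurvivalForest-class].
#' @param time,event,X the forest's training records.
#' @param horizon evaluation horizon in days; default the median
#'   follow-up time.
#' @param seed permutation seed.
#' @param nRepeats permutations averaged per feature (default 1).
#' @param ipcw logical: inverse-probability-of-censoring weighting instead
#'   of restriction (default \code{FALSE}).
#' @return data.frame: feature, vimp, rank_vimp (1 = most important), and
#'   attribute \code{baselineError}.
#' @export
permutationImportance <- function(forest, time, event, X, horizon = NULL,
                                  seed = 1L, nRepeats = 1L, ipcw = FALSE) {
  stopifnot(is(forest, "SurvivalForest"))
  X <- .checkFeatures(X, forest@featureNames)
  .checkSurvivalData(time, event, X)
  horizon <- horizon %||% median(time)
  n <- length(time); B <- nTrees(forest)

  inbag <- lapply(forest@inbag, unique)
  oob <- matrix(TRUE, n, B)
  for (b in seq_len(B)) oob[inbag[[b]], b] <- FALSE
  if (any(rowSums(oob) == 0))
    warning(sum(rowSums(oob) == 0),
            " record(s) are in-bag for every tree and are excluded")

  status <- ifelse(event == 1 & time <= horizon, 1,
                   ifelse(time >= horizon, 0, NA))
  keep <- !is.na(status) & rowSums(oob) > 0
  if (!any(keep)) stop("no records with determinable status at the horizon")

  wts <- rep(1, n)
  if (ipcw) {
    # censoring distribution G by reversed-role Kaplan-Meier
    G <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
    Gat <- function(s) {
      i <- findInterval(s, G$time)
      c(1, G$surv)[i + 1L]
    }
    keep <- rowSums(oob) > 0 & !(event == 0 & time < horizon)
    status <- ifelse(event == 1 & time <= horizon, 1, 0)
    wts <- ifelse(event == 1 & time <= horizon,
                  1 / pmax(Gat(time), 1e-8), 1 / pmax(Gat(horizon), 1e-8))
  }

  grid <- forest@timeGrid
  kh <- findInterval(horizon, grid)
  lhg <- .leafHazardGlobal(forest)
  hAtHorizon <- function(Xcur) {
    ids <- .routeForest(forest, Xcur)
    Hb <- matrix(0, n, B)
    if (kh > 0L)
      for (b in seq_len(B)) Hb[, b] <- lhg[[b]][ids[, b], kh]
    Hb
  }
  oobW <- oob * rep(forest@weights, each = n)
  oobW <- oobW / rowSums(oobW)
  oobError <- function(Hb) {
    p <- 1 - exp(-rowSums(oobW * Hb))
    sum(wts[keep] * (p[keep] - status[keep])^2) / sum(wts[keep])
  }

  baseline <- oobError(hAtHorizon(X))
  p <- ncol(X)
  set.seed(as.integer(seed))
  vimp <- numeric(p)
  for (j in seq_len(p)) {
    if (length(unique(X[, j])) < 2L) {
      warning("feature '", forest@featureNames[j],
              "' is constant; its importance is 0 by construction")
      next
    }
    errs <- vapply(seq_len(nRepeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(n), j]
      oobError(hAtHorizon(Xp))
    }, numeric(1))
    vimp[j] <- mean(errs) - baseline
  }
  out <- data.frame(feature = forest@featureNames, vimp = vimp,
                    rank_vimp = rank(-vimp, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(out, "baselineError") <- baseline
  attr(out, "horizon") <- horizon
  out
}

#' Minimal depth of each feature
#'
#' For each tree, the depth of the shallowest node splitting on the
#' feature (root = 0); a feature unused in a tree contributes that tree's
#' maximum depth plus one. The per-feature values are averaged across
#' trees: variables with high impact on the prediction split nodes
#' nearest the root, so smaller is more important. A structure-only
#' statistic, invariant to the tree weights.
#'
#' @param forest a fitted [SurvivalForest-class].
#' @return data.frame: feature, minimal_depth, rank_depth (1 = smallest).
#' @export
minimalDepth <- function(forest) {
  stopifnot(is(forest, "SurvivalForest"))
  p <- length(forest@featureNames)
  depthSum <- numeric(p)
  for (tr in forest@trees) {
    md <- rep(Inf, p)
    walk <- function(node) {
      if (node$leaf) return(invisible())
      md[node$feature] <<- min(md[node$feature], node$depth)
      walk(node$left); walk(node$right)
    }
    walk(tr@root)
    md[!is.finite(md)] <- tr@params$depth + 1
    depthSum <- depthSum + md
  }
  d <- depthSum / nTrees(forest)
  data.frame(feature = forest@featureNames, minimal_depth = d,
             rank_depth = rank(d, ties.method = "first"),
             stringsAsFactors = FALSE)
}

#' Combined importance report
#'
#' Joins [permutationImportance()] and [minimalDepth()] into one table.
#'
#' @inheritParams permutationImportance
#' @return data.frame: feature, vimp, minimal_depth, rank_vimp,
#'   rank_depth.
#' @export
importanceReport <- function(forest, time, event, X, horizon = NULL,
                             seed = 1L, nRepeats = 1L, ipcw = FALSE) {
  vi <- permutationImportance(forest, time, event, X, horizon = horizon,
                              seed = seed, nRepeats = nRepeats, ipcw = ipcw)
  md <- minimalDepth(forest)
  out <- merge(vi, md, by = "feature", sort = FALSE)
  out <- out[, c("feature", "vimp", "minimal_depth",
                 "rank_vimp", "rank_depth")]
  attr(out, "baselineError") <- attr(vi, "baselineError")
  attr(out, "horizon") <- attr(vi, "horizon")
  out
}

#' Extract decision rules from the main tree
#'
#' Enumerates the root-to-leaf paths of the highest-weight tree, ranks the
#' leaves by their mortality score (the sum of the leaf cumulative hazard
#' over the tree's event-time grid) and returns the top paths as
#' conjunctive rules. Conditions along a path are consolidated into one
#' non-contradictory interval per feature. When training records are
#' supplied, leaf statistics (membership, events) are computed on the
#' records out-of-bag for that tree.
#'
#' @param forest a fitted [SurvivalForest-class].
#' @param topK number of highest-risk rules to return (0 gives an empty
#'   list; more than the leaf count gives all leaves).
#' @param time,event,X optional training records for out-of-bag leaf
#'   statistics.
#' @return list of rules; each rule is a list with \code{conditions}
#'   (data.frame feature, comparator, threshold), \code{mortality},
#'   \code{n}, \code{events}, \code{oob_n}, \code{oob_events}.
#' @export
extractRules <- function(forest, topK = 5L, time = NULL, event = NULL,
                         X = NULL) {
  stopifnot(is(forest, "SurvivalForest"), topK >= 0)
  mainIdx <- which.max(forest@weights)
  tr <- forest@trees[[mainIdx]]
  fn <- tr@featureNames

  paths <- list()
  walk <- function(node, conds) {
    if (node$leaf) {
      paths[[length(paths) + 1L]] <<- list(id = node$id, conds = conds,
                                           n = node$n, events = node$events)
      return(invisible())
    }
    walk(node$left, rbind(conds,
         data.frame(feature = fn[node$feature], comparator = "<=",
                    threshold = node$threshold, stringsAsFactors = FALSE)))
    walk(node$right, rbind(conds,
         data.frame(feature = fn[node$feature], comparator = ">",
                    threshold = node$threshold, stringsAsFactors = FALSE)))
  }
  empty <- data.frame(feature = character(0), comparator = character(0),
                      threshold = numeric(0), stringsAsFactors = FALSE)
  walk(tr@root, empty)

  mortality <- rowSums(tr@leafHazard)
  ord <- order(mortality[vapply(paths, `[[`, 1L, "id")], decreasing = TRUE)
  paths <- paths[ord][seq_len(min(topK, length(paths)))]

  oobIds <- NULL; oobEvent <- NULL
  if (!is.null(X)) {
    X <- .checkFeatures(X, forest@featureNames)
    oobRows <- setdiff(seq_len(nrow(X)), unique(forest@inbag[[mainIdx]]))
    oobIds <- .routeTree(tr@root, X[oobRows, , drop = FALSE])
    oobEvent <- event[oobRows]
  }

  lapply(paths, function(pth) {
    conds <- pth$conds
    if (nrow(conds)) {
      # consolidate to one interval per feature (tightest bounds)
      conds <- do.call(rbind, lapply(split(conds, conds$feature), function(g) {
        out <- g[0, ]
        if (any(g$comparator == ">"))
          out <- rbind(out, data.frame(feature = g$feature[1],
                       comparator = ">",
                       threshold = max(g$threshold[g$comparator == ">"])))
        if (any(g$comparator == "<="))
          out <- rbind(out, data.frame(feature = g$feature[1],
                       comparator = "<=",
                       threshold = min(g$threshold[g$comparator == "<="])))
        out
      }))
      rownames(conds) <- NULL
    }
    rule <- list(conditions = conds, mortality = mortality[pth$id],
                 n = pth$n, events = pth$events)
    if (!is.null(oobIds)) {
      hit <- oobIds == pth$id
      rule$oob_n <- sum(hit)
      rule$oob_events <- sum(oobEvent[hit])
    }
    class(rule) <- "DecisionRule"
    rule
  })
}

#' @export
format.DecisionRule <- function(x, ...) {
  cond <- if (nrow(x$conditions))
    paste(sprintf("%s %s %.4g", x$conditions$feature,
                  x$conditions$comparator, x$conditions$threshold),
          collapse = " & ")
  else "(all records)"
  extra <- if (!is.null(x$oob_n))
    sprintf("; OOB n=%d, events=%d", x$oob_n, x$oob_events) else ""
  sprintf("IF %s THEN mortality=%.4g (n=%d, events=%d%s)",
          cond, x$mortality, x$n, x$events, extra)
}

#' @export
print.DecisionRule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
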