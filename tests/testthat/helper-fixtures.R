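# Shared fixtures, all generated in code.

# small cohort with a single strong volatility signal: one analyte whose
# within-patient SD drives the hazard, everything else noise
signalSpec <- function(n, seed, effect = 1.0, nTreesAnalytes = NULL) {
  cohortSpec(n, seed = seed,
             effectSizes = c(hba1c_sd = effect),
             visitsMean = 10)
}

# survival records with one informative feature and pure-noise companions;
# returns list(time, event, X) with known generative column "signal"
signalRecords <- function(n, seed, nNoise = 4, beta = 1.2) {
  set.seed(seed)
  signal <- rnorm(n)
  X <- cbind(signal = signal,
             matrix(rnorm(n * nNoise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(nNoise)))))
  lp <- beta * signal
  T <- 1000 * (-log(runif(n)) / exp(lp))^(1 / 1.3)
  cens <- 1500
  list(time = pmin(T, cens), event = as.integer(T <= cens), X = X)
}

# tiny perfectly separable fixture: feature 1 splits early events from
# late censorings
separableRecords <- function(nPerArm = 8) {
  n <- 2L * nPerArm
  X <- cbind(sep = rep(c(0, 1), each = nPerArm),
             junk = rep(0.5, n))
  list(time = c(seq_len(nPerArm),                     # early events
                rep(100, nPerArm)),                   # late censorings
       event = c(rep(1L, nPerArm), rep(0L, nPerArm)),
       X = X)
}

# independent brute-force Nelson-Aalen: literal sum of d/Y by loop
oracleNelsonAalen <- function(time, event, at) {
  evTimes <- sort(unique(time[event == 1]))
  H <- 0
  out <- numeric(length(at))
  for (s in evTimes) {
    d <- sum(time == s & event == 1)
    Y <- sum(time >= s)
    H <- H + d / Y
    out[at >= s] <- H
  }
  out
}

# independent O-E / sqrt(V) log-rank by explicit per-time loop
oracleLogrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  g <- c(rep(1, length(t1)), rep(0, length(t2)))
  O <- 0; E <- 0; V <- 0
  for (s in sort(unique(time[event == 1]))) {
    atRisk <- time >= s
    Y <- sum(atRisk); Y1 <- sum(atRisk & g == 1)
    d <- sum(time == s & event == 1)
    d1 <- sum(time == s & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * Y1 / Y
    if (Y > 1) V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  if (V <= 0) return(0)
  abs(O - E) / sqrt(V)
}

# brute-force O(n^2) Harrell C with the package's pair convention
oracleCIndex <- function(risk, time, event) {
  conc <- 0; ties <- 0; comp <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || event[i] != 1 || !(time[i] < time[j])) next
    comp <- comp + 1
    if (risk[i] > risk[j]) conc <- conc + 1
    else if (risk[i] == risk[j]) ties <- ties + 1
  }
  if (comp == 0) return(NA_real_)
  (conc + 0.5 * ties) / comp
}

# exhaustive best log-rank split over all (feature, threshold) pairs
oracleBestSplit <- function(time, event, X, minLeafEvents = 1L) {
  best <- list(stat = 0, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    for (th in sort(unique(X[, j]))) {
      left <- X[, j] <= th
      if (!any(left) || all(left)) next
      if (sum(event[left]) < minLeafEvents ||
          sum(event[!left]) < minLeafEvents) next
      s <- oracleLogrank(time[left], event[left], time[!left], event[!left])
      if (s > best$stat) best <- list(stat = s, feature = j, threshold = th)
    }
  }
  best
}

# deterministic weighted ensemble CHF computed independently of
# predictRisk: loops over trees and evaluates each leaf step function
oracleEnsembleCHF <- function(forest, x, w) {
  grid <- timeGrid(forest)
  H <- numeric(length(grid))
  for (b in seq_len(nTrees(forest))) {
    chf <- predictTreeCHF(forest@trees[[b]], x)
    H <- H + w[b] * chfAt(chf, grid)
  }
  H
}
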