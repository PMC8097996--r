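test_that("concordance handles the canonical extremes", {
  time <- c(1, 2, 3, 4, 5)
  event <- rep(1L, 5)
  # risk perfectly anti-ordered with time, no censoring
  expect_equal(harrellCIndex(rev(time) * 10, time, event), 1)
  # constant risk: every comparable pair is a tie
  expect_equal(harrellCIndex(rep(3, 5), time, event), 0.5)
  # no comparable pairs
  expect_message(ci <- harrellCIndex(1:3, c(5, 5, 5), c(0, 0, 0)),
                 "undefined")
  expect_true(is.na(ci))
})

test_that("concordance equals the brute-force pairwise oracle", {
  set.seed(41)
  for (i in 1:50) {
    n <- 20
    time <- sample(1:10, n, TRUE)
    event <- rbinom(n, 1, 0.6)
    risk <- sample(1:5, n, TRUE)            # force risk ties
    expect_identical(harrellCIndex(risk, time, event),
                     oracleCIndex(risk, time, event))
  }
  # cross-check one draw against the survival package's concordance
  set.seed(43)
  time <- rexp(100); event <- rbinom(100, 1, 0.7); risk <- rnorm(100)
  expect_equal(harrellCIndex(risk, time, event),
               survival::concordance(survival::Surv(time, event) ~ risk,
                                     reverse = TRUE)$concordance)
})

test_that("concordance symmetry and monotone-transform invariance", {
  set.seed(47)
  time <- rexp(50); event <- rbinom(50, 1, 0.7); risk <- rnorm(50)
  expect_equal(harrellCIndex(-risk, time, event),
               1 - harrellCIndex(risk, time, event))
  expect_equal(harrellCIndex(exp(3 * risk), time, event),
               harrellCIndex(risk, time, event))
})

test_that("binary metrics behave at the extremes and under the null", {
  status <- c(0, 0, 0, 1, 1, 1)
  risk <- c(1, 2, 3, 10, 11, 12)
  m <- binaryMetrics(risk, status)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$auc, 1)

  expect_true(is.na(binaryMetrics(risk, rep(1, 6))$auc))

  set.seed(53)
  risk <- rnorm(2000); status <- rbinom(2000, 1, 0.5)
  expect_lt(abs(binaryMetrics(risk, status)$auc - 0.5), 0.03)

  # AUC equals Harrell's C with no censoring and no risk ties
  set.seed(59)
  time <- sample(1:100, 40); risk <- rnorm(40)
  # status = early failure within the whole follow-up makes the analogy
  # exact when every subject is an event: compare on the event indicator
  auc <- binaryMetrics(risk, as.numeric(time <= 50))$auc
  # C computed against the binary "fails early" ordering
  cAll <- harrellCIndex(risk, ifelse(time <= 50, 1, 2), rep(1, 40))
  expect_equal(auc, cAll)
})

test_that("Cox baseline matches a 1-D partial-likelihood grid search", {
  # single binary covariate, hand-checkable fixture
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  cox <- fitCox(time, event, matrix(x, dimnames = list(NULL, "x")))

  negpl <- function(beta) {      # Breslow partial likelihood by loop
    s <- 0
    for (i in which(event == 1)) {
      atRisk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[atRisk])))
    }
    -s
  }
  grid <- seq(-3, 3, by = 1e-4)
  betaOracle <- grid[which.min(vapply(grid, negpl, numeric(1)))]
  expect_lt(abs(unname(cox@coefficients) - betaOracle), 1e-3)
  expect_true(cox@converged)
  expect_true(all(diff(cox@baselineHazard$hazard) >= 0))

  # null covariate at large n gives a near-zero coefficient
  set.seed(61)
  tn <- rexp(400); en <- rbinom(400, 1, 0.7); xn <- rnorm(400)
  coxNull <- fitCox(tn, en, matrix(xn, dimnames = list(NULL, "x")))
  expect_lt(abs(unname(coxNull@coefficients)), 0.15)

  # duplicating the dataset leaves the coefficient unchanged
  coxDup <- fitCox(rep(time, 2), rep(event, 2),
                   matrix(rep(x, 2), dimnames = list(NULL, "x")))
  expect_equal(coxDup@coefficients, cox@coefficients, tolerance = 1e-6)

  expect_error(fitCox(time, event,
                      matrix(1, 6, 1, dimnames = list(NULL, "c"))),
               "constant")
})

test_that("cross-validation folds partition records and stratify events", {
  set.seed(67)
  event <- rbinom(200, 1, 0.3)
  folds <- rwsurf:::.stratifiedFolds(event, 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  expect_length(folds, 200)
  perFoldEvents <- tapply(event, folds, sum)
  expect_lt(max(perFoldEvents) - min(perFoldEvents), 3)
  expect_identical(rwsurf:::.stratifiedFolds(event, 5, seed = 3), folds)
})

test_that("cross-validated comparison runs and Cox recovers a PH cohort", {
  set.seed(71)
  n <- 300
  x <- rnorm(n)
  lp <- 0.9 * x
  T <- 900 * (-log(runif(n)) / exp(lp))^(1 / 1.3)
  time <- pmin(T, 1200); event <- as.integer(T <= 1200)
  X <- cbind(x = x, z = rnorm(n))

  rep <- crossValidate(time, event, X, models = "cox", nFolds = 5,
                       seed = 5)
  expect_s3_class(rep, "EvaluationReport")
  expect_true(all(rep$c_index >= 0 & rep$c_index <= 1, na.rm = TRUE))
  meanRow <- rep[rep$fold == "mean" & rep$model == "cox", ]
  folds <- rep[rep$fold != "mean" & rep$model == "cox", ]
  expect_equal(meanRow$c_index, mean(folds$c_index))

  cOracle <- harrellCIndex(lp, time, event)
  expect_lt(abs(meanRow$c_index - cOracle), 0.03)
})

test_that("identical model specifications give identical reports", {
  rec <- signalRecords(120, seed = 73)
  r1 <- crossValidate(rec$time, rec$event, rec$X, models = "rsf",
                      nFolds = 3, seed = 9, nTrees = 10)
  r2 <- crossValidate(rec$time, rec$event, rec$X, models = "rsf",
                      nFolds = 3, seed = 9, nTrees = 10)
  expect_identical(r1$c_index, r2$c_index)
  expect_identical(r1$auc, r2$auc)
})
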