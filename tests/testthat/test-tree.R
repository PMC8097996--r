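test_that("Nelson-Aalen matches hand computation and handles degenerate input", {
  H <- nelsonAalen(c(1, 2, 3), c(1, 1, 1))
  expect_equal(H@hazard, c(1/3, 1/3 + 1/2, 1/3 + 1/2 + 1))
  expect_equal(chfAt(H, 3), 11/6)
  expect_equal(chfAt(H, 0.5), 0)

  allCens <- nelsonAalen(c(5, 6, 7), c(0, 0, 0))
  expect_length(allCens@times, 0)
  expect_equal(chfAt(allCens, 100), 0)

  one <- nelsonAalen(5, 1)
  expect_equal(chfAt(one, 5), 1)
  expect_error(nelsonAalen(numeric(0), numeric(0)), "at least one")
})

test_that("Nelson-Aalen equals the closed form sum d/Y on random fixtures", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(1:10, 1)
    time <- sample(1:6, n, replace = TRUE)        # force ties
    event <- rbinom(n, 1, 0.6)
    H <- nelsonAalen(time, event)
    at <- sort(unique(c(time, 0, 7)))
    expect_equal(chfAt(H, at), oracleNelsonAalen(time, event, at))
  }
  # and against the survival package's estimator on a larger draw
  set.seed(18)
  t2 <- rexp(60); e2 <- rbinom(60, 1, 0.5)
  sf <- survival::survfit(survival::Surv(t2, e2) ~ 1, ctype = 1)
  expect_equal(chfAt(nelsonAalen(t2, e2), sf$time[sf$n.event > 0]),
               sf$cumhaz[sf$n.event > 0])
})

test_that("log-rank statistic agrees with independent oracles", {
  # identical groups: no separation
  expect_equal(logrankStatistic(c(1, 2, 3), c(1, 1, 0),
                                c(1, 2, 3), c(1, 1, 0)), 0)
  # clear separation is positive
  expect_gt(logrankStatistic(c(1, 2), c(1, 1), c(10, 10), c(0, 0)), 0)
  # no events at all: defined as 0
  expect_equal(logrankStatistic(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), 0)

  # 6-record toy set vs the hand-rolled O-E/sqrt(V) oracle
  t1 <- c(1, 3, 5); e1 <- c(1, 0, 1)
  t2 <- c(2, 4, 6); e2 <- c(1, 1, 0)
  expect_equal(logrankStatistic(t1, e1, t2, e2),
               oracleLogrank(t1, e1, t2, e2))

  # random fixtures vs oracle and vs survival::survdiff
  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    t1 <- sample(1:5, n1, TRUE); e1 <- rbinom(n1, 1, 0.7)
    t2 <- sample(1:5, n2, TRUE); e2 <- rbinom(n2, 1, 0.7)
    s <- logrankStatistic(t1, e1, t2, e2)
    expect_equal(s, oracleLogrank(t1, e1, t2, e2))
    if (sum(e1) + sum(e2) > 0 && s > 0) {
      sd2 <- survival::survdiff(
        survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(n1, n2)))
      expect_equal(s, sqrt(sd2$chisq))
    }
  }
  expect_error(logrankStatistic(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("a perfectly separating feature yields a depth-1 tree", {
  rec <- separableRecords()
  set.seed(1)
  tree <- growTree(rec$time, rec$event, rec$X, mtry = 2,
                   minLeafEvents = 0, exhaustive = TRUE)
  expect_false(tree@root$leaf)
  expect_equal(tree@root$feature, 1L)        # the separating feature
  expect_true(tree@root$left$leaf && tree@root$right$leaf)
  expect_equal(tree@params$depth, 1L)
})

test_that("degenerate inputs give a single leaf; fixed seed reproduces", {
  n <- 10
  X <- matrix(1, n, 2)
  set.seed(2)
  tree <- growTree(rep(5, n), rep(1L, n), X)
  expect_true(tree@root$leaf)

  rec <- signalRecords(60, seed = 4)
  set.seed(99); t1 <- growTree(rec$time, rec$event, rec$X)
  set.seed(99); t2 <- growTree(rec$time, rec$event, rec$X)
  expect_identical(t1@root, t2@root)
  expect_identical(t1@leafHazard, t2@leafHazard)
})

test_that("greedy split matches exhaustive search on tiny datasets", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    time <- sample(1:6, n, TRUE)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) event[1:2] <- 1L
    X <- matrix(sample(1:4, 2 * n, TRUE), n, 2)
    oracle <- oracleBestSplit(time, event, X, minLeafEvents = 1L)
    tree <- growTree(time, event, X, mtry = 2, minLeafEvents = 1,
                     maxDepth = 1, exhaustive = TRUE)
    if (oracle$stat > 0 && !tree@root$leaf) {
      st <- rwsurf:::.logrankSplitStats(time, event, X[, tree@root$feature],
                                        tree@root$threshold)
      expect_equal(st$stat[1], oracle$stat, tolerance = 1e-12)
    } else {
      # no admissible separating split found by either route
      expect_true(oracle$stat == 0 || tree@root$leaf)
    }
  }
})

test_that("tree prediction routes ties left and dominates as constructed", {
  rec <- separableRecords()
  set.seed(1)
  tree <- growTree(rec$time, rec$event, rec$X, mtry = 2,
                   minLeafEvents = 0, exhaustive = TRUE)
  thr <- tree@root$threshold
  atBoundary <- c(thr, 0.5)
  leftLeaf <- predictTreeCHF(tree, atBoundary)
  expect_equal(chfAt(leftLeaf, max(rec$time)),
               chfAt(predictTreeCHF(tree, c(thr - 1, 0.5)),
                     max(rec$time)))   # boundary routed left

  early <- predictTreeCHF(tree, c(0, 0.5))   # early-event arm
  late <- predictTreeCHF(tree, c(1, 0.5))    # late-censor arm
  grid <- tree@timeGrid
  expect_true(all(chfAt(early, grid) >= chfAt(late, grid)))
  expect_gt(chfAt(early, max(grid)), chfAt(late, max(grid)))

  # leaf CHFs are non-decreasing in t (structural invariant)
  expect_true(all(apply(tree@leafHazard, 1, function(h)
    all(diff(h) >= 0))))

  # single-leaf tree returns its leaf for any x
  single <- growTree(rep(5, 4), rep(1L, 4), matrix(1, 4, 2))
  expect_equal(chfAt(predictTreeCHF(single, c(99, -99)), 5),
               chfAt(predictTreeCHF(single, c(-1, -1)), 5))
})
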