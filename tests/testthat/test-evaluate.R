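test_that("kfoldSplit stratifies, balances and is seed-deterministic", {
  labs <- rep(c(1, -1), each = 10)
  f <- kfoldSplit(labs, k = 5, seed = 3)
  tab <- table(f, labs)
  expect_true(all(tab == 2))  # 10 per class over 5 folds

  labs2 <- c(rep(1, 11), rep(-1, 15))
  f2 <- kfoldSplit(labs2, k = 5, seed = 3)
  pos_sizes <- sort(as.integer(table(f2[labs2 > 0])), decreasing = TRUE)
  expect_identical(pos_sizes, c(3L, 2L, 2L, 2L, 2L))

  expect_identical(kfoldSplit(labs, seed = 9), kfoldSplit(labs, seed = 9))
  expect_false(identical(kfoldSplit(labs, seed = 9), kfoldSplit(labs, seed = 10)))
  expect_error(kfoldSplit(c(1, 1, 1, -1), k = 5), "at least k")
})

test_that("computeMetrics matches the defining formulas", {
  perfect <- computeMetrics(TP = 50, TN = 50, FP = 0, FN = 0)
  expect_equal(unname(perfect), c(100, 100, 100, 1))
  inverted <- computeMetrics(TP = 0, TN = 0, FP = 50, FN = 50)
  expect_equal(unname(inverted), c(0, 0, 0, -1))

  ## hand-derived from the formulas on a 191+191-style confusion table
  m <- computeMetrics(TP = 191, FN = 0, TN = 143, FP = 48)
  expect_equal(m[["ACC"]], 100 * 334 / 382, tolerance = 1e-9)
  expect_equal(m[["SN"]], 100)
  expect_equal(m[["SP"]], 100 * 143 / 191, tolerance = 1e-9)
  expect_equal(m[["MCC"]], 27313 / sqrt(239 * 191 * 191 * 143),
               tolerance = 1e-9)
  expect_equal(m[["MCC"]], 0.7735, tolerance = 1e-4)

  ## degenerate denominators: MCC defined as 0
  expect_equal(computeMetrics(TP = 5, TN = 0, FP = 5, FN = 0)[["MCC"]], 0)
  expect_error(computeMetrics(TP = 0, TN = 0, FP = 0, FN = 0), "zero")
})

test_that("metrics agree with brute-force recounts over random tables", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    true <- sample(c(1, -1), n, replace = TRUE)
    pred <- sample(c(1, -1), n, replace = TRUE)
    cc <- confusionCounts(true, pred)
    expect_identical(cc, bruteConfusion(true, pred))
    m <- computeMetrics(cc)
    expect_true(m[["ACC"]] >= 0 && m[["ACC"]] <= 100)
    expect_true(m[["MCC"]] >= -1 && m[["MCC"]] <= 1)
    ## accuracy is the class-size-weighted mean of SN and SP
    P <- sum(true > 0); N <- sum(true < 0)
    if (P > 0 && N > 0)
      expect_equal(m[["ACC"]], (P * m[["SN"]] + N * m[["SP"]]) / (P + N),
                   tolerance = 1e-9)
  }
})

test_that("MCC is near zero when predictions are independent of truth", {
  set.seed(72)
  true <- sample(c(1, -1), 10000, replace = TRUE)
  pred <- sample(c(1, -1), 10000, replace = TRUE)
  expect_lt(abs(computeMetrics(confusionCounts(true, pred))[["MCC"]]), 0.1)
})

test_that("crossValidate partitions records and averages fold metrics", {
  fx <- makeSyntheticAAC(nPos = 15, nNeg = 15, seed = 73)
  cv <- crossValidate(fx$features, fx$labels, k = 5, seed = 73)
  fa <- foldAssignments(cv)
  ## partition: every record tested exactly once
  expect_setequal(names(fa), rownames(featureMatrix(fx$features)))
  expect_setequal(cvScores(cv)$id, names(fa))
  expect_identical(anyDuplicated(cvScores(cv)$id), 0L)
  expect_identical(sort(unique(unname(fa))), 1:5)

  fm <- cv@foldMetrics
  expect_identical(nrow(fm), 5L)
  expect_equal(unname(meanMetrics(cv)["ACC"]), mean(fm$ACC))
  ## fold metrics agree with a recount of that fold's scores
  for (f in 1:5) {
    sc <- cvScores(cv)[cvScores(cv)$fold == f, ]
    expect_equal(computeMetrics(bruteConfusion(sc$true, sc$predicted)),
                 unlist(fm[fm$fold == f, c("ACC", "SN", "SP", "MCC")]))
  }
})

test_that("crossValidate is invariant to example order under the same seed", {
  fx <- makeSyntheticAAC(nPos = 10, nNeg = 10, seed = 74)
  mat <- featureMatrix(fx$features)
  cv1 <- crossValidate(mat, fx$labels, svmConfig(), seed = 5)
  perm <- sample(nrow(mat))
  cv2 <- crossValidate(mat[perm, ], fx$labels[perm], svmConfig(), seed = 5)
  expect_equal(meanMetrics(cv1), meanMetrics(cv2), tolerance = 1e-9)
  expect_identical(foldAssignments(cv1)[sort(names(foldAssignments(cv1)))],
                   foldAssignments(cv2)[sort(names(foldAssignments(cv2)))])
})

test_that("a perfectly separable set cross-validates at 100 percent", {
  x <- rbind(matrix(rep(c(1, 0), each = 10), ncol = 2),
             matrix(rep(c(0, 1), each = 10), ncol = 2))
  rownames(x) <- paste0("e", 1:20)
  labs <- rep(c(1, -1), each = 10)
  cv <- crossValidate(x, labs, svmConfig("linear"), seed = 2)
  expect_equal(unname(meanMetrics(cv)["ACC"]), 100)
})

test_that("threshold sweep hits its endpoints and is monotone in SN/SP", {
  set.seed(75)
  scores <- data.frame(decision = c(rnorm(40, 1), rnorm(40, -1)),
                       true = rep(c(1, -1), each = 40))
  grid <- seq(min(scores$decision) - 0.5, max(scores$decision) + 0.5,
              length.out = 81)
  sw <- thresholdSweep(scores, grid)
  expect_identical(nrow(sw), 81L)
  expect_equal(sw$SN[1], 100)   # everything predicted positive
  expect_equal(sw$SP[1], 0)
  expect_equal(sw$SN[81], 0)    # everything predicted negative
  expect_equal(sw$SP[81], 100)
  expect_true(all(diff(sw$SN) <= 1e-9))
  expect_true(all(diff(sw$SP) >= -1e-9))

  ## default grid spans the observed decision values
  sw2 <- thresholdSweep(scores)
  expect_identical(nrow(sw2), 101L)
  expect_equal(sw2$threshold[1], min(scores$decision))
  expect_error(thresholdSweep(data.frame(decision = 1)), "true")
})

test_that("scoreGraph counts misclassifications and FPR by direct counting", {
  scores <- data.frame(decision = c(1.2, 0.8, -0.9, 0.3),
                       true = c(1, 1, -1, -1))
  g <- scoreGraph(scores, threshold = 0)
  expect_identical(g$falseNegatives, 0L)
  expect_identical(g$falsePositives, 1L)
  expect_equal(g$FPR, 0.5)

  ## all negatives below threshold -> FPR 0
  g0 <- scoreGraph(data.frame(decision = c(2, -1, -2), true = c(1, -1, -1)))
  expect_equal(g0$FPR, 0)

  ## brute-force agreement on a synthetic 100+100 run
  set.seed(76)
  big <- data.frame(decision = rnorm(200), true = rep(c(1, -1), each = 100))
  g2 <- scoreGraph(big, threshold = 0.2)
  fp <- sum(big$true < 0 & big$decision >= 0.2)
  tn <- sum(big$true < 0 & big$decision < 0.2)
  expect_identical(g2$falsePositives, fp)
  expect_equal(g2$FPR, fp / (fp + tn))
  expect_identical(nrow(g2$series), 200L)
})
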