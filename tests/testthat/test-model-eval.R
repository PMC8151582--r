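test_that("all three classifiers separate a linearly separable toy set", {
  set.seed(61)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2),
             matrix(rnorm(40, 6), ncol = 2))
  y <- factor(rep(c("term", "preterm"), each = 20), c("term", "preterm"))
  for (kind in c("KNN", "LDA", "LR")) {
    pred <- fitPredict(classifierSpec(kind), x, y, x)
    expect_identical(as.character(pred$labels), as.character(y))
    expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  }
})

test_that("KNN scores are the preterm neighbour fraction", {
  ## eval point at the origin; its 5 nearest neighbours: 3 preterm, 2 term
  train <- rbind(matrix(0.1 * c(1, -1, 0, 1, 0, -1), ncol = 2,
                        byrow = TRUE),          # 3 preterm nearby
                 matrix(0.1 * c(2, 0, 0, 2), ncol = 2, byrow = TRUE),
                 matrix(50 + rnorm(20), ncol = 2))  # far-away term mass
  y <- factor(c(rep("preterm", 3), rep("term", 12)),
              c("term", "preterm"))
  pred <- fitPredict(classifierSpec("KNN", standardize = FALSE),
                     train, y, matrix(0, 1, 2))
  expect_identical(as.character(pred$labels), "preterm")
  expect_equal(pred$scores, 0.6)
})

test_that("LDA and LR are invariant to training row order", {
  set.seed(62)
  x <- matrix(rnorm(120), ncol = 3)
  y <- factor(rep(c("term", "preterm"), each = 20), c("term", "preterm"))
  xe <- matrix(rnorm(30), ncol = 3)
  perm <- sample(40)
  for (kind in c("LDA", "LR")) {
    a <- fitPredict(classifierSpec(kind), x, y, xe)
    b <- fitPredict(classifierSpec(kind), x[perm, ], y[perm], xe)
    expect_equal(a$scores, b$scores, tolerance = 1e-9)
  }
})

test_that("majority vote follows 2-of-3 logic with mean-score ensembles", {
  l <- function(...) factor(c(...), c("term", "preterm"))
  mv <- majorityVote(list(l("preterm"), l("preterm"), l("term")))
  expect_identical(as.character(mv$labels), "preterm")
  mv0 <- majorityVote(list(l("term"), l("term"), l("term")))
  expect_identical(as.character(mv0$labels), "term")

  ## when two bases disagree, the third decides
  set.seed(63)
  for (i in 1:20) {
    a <- l(sample(c("term", "preterm"), 1))
    b <- l(if (a == "term") "preterm" else "term")
    c_ <- l(sample(c("term", "preterm"), 1))
    mv <- majorityVote(list(a, b, c_))
    expect_identical(as.character(mv$labels), as.character(c_))
  }

  sc <- majorityVote(list(l("preterm"), l("preterm"), l("term")),
                     list(0.9, 0.8, 0.1))
  expect_equal(sc$scores, 0.6)
  expect_error(majorityVote(list(l("term"), l("term", "term"),
                                 l("term"))), "length")
})

test_that("confusion metrics and AUC match hand values and pROC", {
  truth <- factor(rep(c("preterm", "term"), each = 50),
                  c("term", "preterm"))
  pred <- factor(c(rep("preterm", 45), rep("term", 5),
                   rep("term", 45), rep("preterm", 5)),
                 c("term", "preterm"))
  scores <- ifelse(pred == "preterm", 0.9, 0.1)
  m <- computeMetrics(truth, pred, scores)
  expect_equal(unname(m[c("accuracy", "f1", "sensitivity",
                          "specificity")]),
               rep(0.9, 4))

  ## perfect separation
  sPerf <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(unname(computeMetrics(truth, pred, sPerf)["auc"]), 1)

  ## random scores: AUC ~ 0.5
  set.seed(64)
  truthBig <- factor(rep(c("preterm", "term"), each = 1000),
                     c("term", "preterm"))
  sRand <- runif(2000)
  predRand <- factor(ifelse(sRand >= 0.5, "preterm", "term"),
                     c("term", "preterm"))
  mr <- computeMetrics(truthBig, predRand, sRand)
  expect_equal(unname(mr["auc"]), 0.5, tolerance = 0.03)

  ## rank AUC equals trapezoidal ROC integration (pROC)
  aucP <- as.numeric(pROC::auc(pROC::roc(
    response = truthBig, predictor = sRand, levels = c("term", "preterm"),
    direction = "<", quiet = TRUE)))
  expect_equal(unname(mr["auc"]), aucP, tolerance = 1e-12)

  expect_error(computeMetrics(factor(rep("term", 4),
                                     c("term", "preterm")),
                              predRand[1:4], sRand[1:4]),
               "single class")
})

test_that("Friedman/Nemenyi comparison matches the textbook formula", {
  ## hand-rankable 4 x 3 table, no ties
  m <- matrix(c(0.9, 0.8, 0.7,
                0.85, 0.85 - 0.05, 0.6,
                0.95, 0.9, 0.85,
                0.7, 0.65, 0.6), ncol = 3, byrow = TRUE)
  m <- rbind(m, m + 0.001)   # 8 partitions
  res <- compareClassifiers(m)
  expect_equal(res$friedmanStatistic, oracleFriedman(m), tolerance = 1e-9)
  expect_equal(res$friedmanStatistic,
               unname(friedman.test(m)$statistic), tolerance = 1e-9)
  expect_true(isSymmetric(res$pMatrix))

  ## identical columns: completely tied, nothing significant
  same <- matrix(rep(runif(30), 3), ncol = 3)
  resSame <- compareClassifiers(same)
  expect_equal(resSame$friedmanP, 1)
  expect_false(any(resSame$significant))

  ## one strictly dominant classifier vs two identical others
  set.seed(65)
  base <- matrix(runif(60, 0.6, 0.7), ncol = 2)
  dom <- cbind(base[, 1] + 0.2, base, deparse.level = 0)
  colnames(dom) <- c("A", "B", "C")
  resDom <- compareClassifiers(dom)
  expect_true(resDom$significant["A", "B"])
  expect_true(resDom$significant["A", "C"])
  expect_false(resDom$significant["B", "C"])
})

test_that("coefficient-of-variation reporting is exact and scale-free", {
  df <- data.frame(
    classifier = rep(c("KNN", "LDA", "ensemble"), each = 2),
    partition = rep(1:2, 3),
    f1 = c(0.8, 1.0, 0.9, 0.9, 0.85, 0.95),
    auc = c(0.5, 0.7, 0.6, 0.6, 0.55, 0.65))
  rep_ <- variabilityReport(df)
  cv <- rep_$cv
  expect_equal(cv$f1[cv$classifier == "KNN"], sd(c(0.8, 1)) / 0.9,
               tolerance = 1e-12)
  expect_equal(cv$f1[cv$classifier == "LDA"], 0)

  df2 <- df
  df2$f1 <- df2$f1 * 2
  expect_equal(variabilityReport(df2)$cv$f1, cv$f1, tolerance = 1e-12)

  expect_equal(rep_$baseRange$f1,
               c(0, mean(c(cv$f1[1], 0)), cv$f1[1]),
               tolerance = 1e-12)
})
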