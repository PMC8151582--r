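test_that("fitness is mean validation F1 times the reduction term", {
  expect_equal(pretermEHG:::.gaFitness(0.9, 203, 29), 156.6)
  expect_equal(pretermEHG:::.gaFitness(0.7, 203, 203), 0)
  ## equal F1, fewer features: strictly higher fitness
  expect_gt(pretermEHG:::.gaFitness(0.8, 203, 20),
            pretermEHG:::.gaFitness(0.8, 203, 40))

  ## end-to-end on a separable table: full mask zeroes the fitness
  se <- simulatePlantedTable(nPerClass = 30, seed = 51)
  parts <- makePartitions(SummarizedExperiment::colData(se)$label,
                          nPartitions = 4, seed = 1)
  spec <- classifierSpec("LDA")
  full <- evaluateFitness(rep(1L, 20), spec, se, partitions = parts)
  expect_identical(full$fitness, 0)
  expect_identical(full$nSelected, 20L)

  sub <- evaluateFitness(c(rep(1L, 5), rep(0L, 15)), spec, se,
                         partitions = parts)
  expect_equal(sub$fitness, sub$meanValF1 * (20 - 5))

  expect_message(
    zero <- evaluateFitness(rep(0L, 20), spec, se, partitions = parts),
    "all-zero")
  expect_identical(zero$fitness, -Inf)
})

test_that("configuration constructors validate their invariants", {
  expect_error(gaConfig(genomeLength = 20, populationSize = 3), ">= 4")
  expect_error(gaConfig(crossoverProb = 1.2), "crossoverProb")
  expect_error(gaConfig(populationSize = 8, eliteCount = 8),
               "eliteCount")
  expect_error(classifierSpec("KNN", knnK = 4), "odd")
  expect_error(entropyConfig(rFactor = 0), "rFactor")
})

test_that("tournament selection prefers fitness and is uniform under ties", {
  set.seed(52)
  picks <- replicate(200, tournamentSelect(c(10, 0)))
  drawnBoth <- picks   # whenever both are drawn the fit one must win;
  expect_gt(mean(picks == 1L), 0.7)  # only self-draws of #2 return 2

  expect_identical(tournamentSelect(5), 1L)
  expect_error(tournamentSelect(c(1, NA)), "evaluated")

  counts <- table(factor(replicate(1e4, tournamentSelect(rep(1, 4))),
                         1:4))
  chisq <- sum((counts - 2500)^2 / 2500)
  expect_lt(chisq, qchisq(0.999, df = 3))
})

test_that("arithmetic crossover keeps agreement and averages disagreement", {
  set.seed(53)
  p <- rbinom(50, 1, 0.5)
  expect_identical(arithmeticCrossover(p, p), as.integer(p))

  ones <- rep(1L, 40); zeros <- rep(0L, 40)
  child <- arithmeticCrossover(ones, zeros)
  expect_true(all(child == child[1]))   # one convex weight per child

  for (i in 1:200) {
    a <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.5)
    ch <- arithmeticCrossover(a, b)
    agree <- a == b
    expect_identical(ch[agree], as.integer(a[agree]))
    expect_true(all(ch %in% c(0L, 1L)))
  }
  expect_error(arithmeticCrossover(1:3, 1:4), "length")
})

test_that("uniform mutation redraws genes at the configured rate", {
  m <- rbinom(203, 1, 0.5)
  set.seed(54)
  expect_identical(uniformMutation(m, rate = 0), as.integer(m))

  ## rate 1: every gene redrawn Bernoulli(0.5); about half change
  flips1 <- replicate(300, sum(uniformMutation(m, rate = 1) != m))
  expect_equal(mean(flips1), 203 / 2, tolerance = 0.05)

  ## rate 0.01: about 203 * 0.01 * 0.5 ~ 1 changed gene on average
  flips001 <- replicate(3000, sum(uniformMutation(m, rate = 0.01) != m))
  expect_equal(mean(flips001), 203 * 0.01 * 0.5, tolerance = 0.15)
})

test_that("the GA recovers planted informative features deterministically", {
  se <- simulatePlantedTable(seed = 55)
  parts <- makePartitions(SummarizedExperiment::colData(se)$label,
                          nPartitions = 6, seed = 2)
  cfg <- gaConfig(genomeLength = 20, populationSize = 30,
                  mutationRate = 0.05, maxGenerations = 60, seed = 77)
  res <- suppressMessages(
    runGA(se, spec = classifierSpec("KNN"), partitions = parts,
          config = cfg))
  expect_gte(sum(res$bestMask[1:5]), 4)
  ## the reduction term is active: converged subsets stay small
  expect_lt(sum(res$bestMask), 10)
  ## elitism: generation-best fitness never decreases
  expect_false(is.unsorted(res$history$best))

  res2 <- suppressMessages(
    runGA(se, spec = classifierSpec("KNN"), partitions = parts,
          config = cfg))
  expect_identical(res$bestMask, res2$bestMask)

  ## a different wrapper classifier runs on its own and yields a valid mask
  resLDA <- suppressMessages(
    runGA(se, spec = classifierSpec("LDA"), partitions = parts,
          config = gaConfig(genomeLength = 20, populationSize = 20,
                            mutationRate = 0.05, maxGenerations = 15,
                            seed = 78)))
  expect_true(all(resLDA$bestMask %in% c(0L, 1L)))
  expect_gte(sum(resLDA$bestMask), 1)
})

test_that("GA termination stalls on a flat fitness landscape", {
  ## constant features: every mask gives the same F1, so after the first
  ## improvement the best fitness can only move by < tol and the stall
  ## counter must fire well before the generation cap
  se <- toyFeatureSE(12, 12, p = 6, seed = 56, shift = 8)
  parts <- makePartitions(SummarizedExperiment::colData(se)$label,
                          nPartitions = 3, seed = 3)
  res <- suppressMessages(
    runGA(se, spec = classifierSpec("LDA"), partitions = parts,
          config = gaConfig(genomeLength = 6, populationSize = 8,
                            stallGenerations = 10, maxGenerations = 200,
                            seed = 79)))
  expect_true(res$converged)
  expect_lt(res$generations, 200)
})
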