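test_that("default truth reproduces the reference parameter structure", {
  tr <- defaultTruth()
  expect_equal(unname(diag(tr$G0)), c(0.035, 0.004, 2.024))
  expect_equal(unname(stats::cov2cor(tr$G0)[lower.tri(tr$G0)]),
               c(0.82, -0.39, -0.17))
  ## heritabilities by construction of P0
  P0 <- tr$G0 + tr$K0 + tr$R0
  expect_equal(unname(diag(tr$G0) / diag(P0)), c(0.32, 0.26, 0.56))
  expect_equal(unname(stats::cov2cor(P0)[lower.tri(P0)]),
               c(0.68, -0.30, -0.17))
  ## pen + residual reconstruct the non-genetic remainder exactly
  expect_equal(tr$K0 + tr$R0, tr$P0 - tr$G0)
  for (M in list(tr$G0, tr$K0, tr$R0)) {
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("zero variances reduce phenotypes to their fixed parts", {
  tr <- defaultTruth()
  tr$G0 <- tr$K0 <- tr$R0 <- matrix(0, 3L, 3L)
  cfg <- smallConfig(selection = NULL)
  cfg$truth <- tr
  sim <- simulatePopulation(cfg, seed = 9L)
  ph <- sim$phenotypes
  ## within identical fixed cells, adfi minus its covariate term is constant
  cell <- interaction(ph$year_quarter, ph$gender, ph$parity, drop = TRUE)
  resid <- ph$adfi - 0.010 * ph$start_bw
  spread <- tapply(resid, cell, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-10)
  expect_true(all(sim$truth$additive[animalIds(sim$pedigree), ] == 0))
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- smallConfig()
  s1 <- simulatePopulation(cfg, seed = 4L)
  s2 <- simulatePopulation(cfg, seed = 4L)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$additive, s2$truth$additive)
  s3 <- simulatePopulation(cfg, seed = 5L)
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})

test_that("founder additive values realize the generating G0", {
  cfg <- simConfig(nFounders = 5000L, nGenerations = 1L,
                   matingsPerGeneration = 1L, offspringPerMating = 1L,
                   propMale = 0.5, selection = NULL)
  sim <- simulatePopulation(cfg, seed = 13L)
  aF <- sim$truth$additive[seq_len(5000L), ]
  G0 <- defaultTruth()$G0
  relErr <- norm(stats::cov(aF) - G0, "F") / norm(G0, "F")
  expect_lt(relErr, 0.05)
})

test_that("Mendelian sampling has the parent-average and half-G0 structure", {
  G0 <- defaultTruth()$G0
  sA <- c(0.2, 0.01, 1.1)
  dA <- c(-0.1, 0.02, -0.4)
  ## no genetic variance: offspring is exactly the parent average
  set.seed(1)
  expect_equal(mendelianSample(sA, dA, 0, 0, matrix(0, 3L, 3L)),
               0.5 * (sA + dA))
  ## fully inbred parents: the sampling variance vanishes
  expect_equal(mendelianSample(sA, dA, 1, 1, G0), 0.5 * (sA + dA))
  ## Monte-Carlo covariance of the deviations approaches G0 / 2
  set.seed(2)
  devs <- t(replicate(10000L,
                      mendelianSample(sA, dA, 0, 0, G0))) -
    matrix(0.5 * (sA + dA), 10000L, 3L, byrow = TRUE)
  relErr <- norm(stats::cov(devs) - 0.5 * G0, "F") / norm(0.5 * G0, "F")
  expect_lt(relErr, 0.05)
})

test_that("stacked additive values are consistent with A kron G0", {
  ## whiten by the pedigree: rows of solve(t(chol(A)), a) are iid N(0, G0)
  cfg <- simConfig(nFounders = 300L, nGenerations = 2L,
                   matingsPerGeneration = 50L, offspringPerMating = 6L,
                   propMale = 0.5, selection = NULL)
  sim <- simulatePopulation(cfg, seed = 23L)
  A <- relationshipMatrix(sim$pedigree)
  z <- solve(t(chol(A)), sim$truth$additive)
  G0 <- defaultTruth()$G0
  relErr <- norm(stats::cov(z) - G0, "F") / norm(G0, "F")
  expect_lt(relErr, 0.15)
})

test_that("directional selection produces a monotone true genetic trend", {
  cfg <- simConfig(nFounders = 150L, nGenerations = 4L,
                   matingsPerGeneration = 30L, offspringPerMating = 8L,
                   propMale = 0.5,
                   selection = list(trait = "ADFI", direction = "min",
                                    basis = "true_bv", fraction = 0.2))
  sim <- simulatePopulation(cfg, seed = 29L)
  ped <- sim$pedigree
  phenIds <- sim$phenotypes$animal
  years <- birthYears(ped)[match(phenIds, animalIds(ped))]
  tr <- geneticTrend(sim$truth$additive[phenIds, "ADFI"],
                     trendBasis(years))
  expect_true(all(diff(tr) < 0))
})

test_that("an unsustainable mating plan fails loudly", {
  cfg <- simConfig(nFounders = 8L, nGenerations = 2L,
                   matingsPerGeneration = 12L, offspringPerMating = 2L,
                   propMale = 0.95, selection = NULL)
  expect_error(simulatePopulation(cfg, seed = 31L), "extinct")
})
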