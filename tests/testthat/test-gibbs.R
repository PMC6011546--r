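toyPhenotypes <- function(n = 12L, pens = 1L) {
  data.frame(animal = sprintf("T%02d", seq_len(n)),
             pen = sprintf("P%d", rep_len(seq_len(pens), n)),
             year_quarter = "2008Q1", gender = "M", parity = 1L,
             start_bw = 50 + seq_len(n), end_bw = 100 + seq_len(n),
             adfi = 2.5 + rnorm(n, 0, 0.1), adg = 1.1 + rnorm(n, 0, 0.05),
             lmp = 62 + rnorm(n, 0, 1))
}

toyPed <- function(n = 12L) {
  pedigree(sprintf("T%02d", seq_len(n)), rep(0, n), rep(0, n),
           rep(2008L, n))
}

test_that("design construction maps factors, covariates and pens", {
  set.seed(1)
  ## single-level factors: first factor carries the intercept, the others
  ## are dropped with a warning
  expect_warning(expect_warning(
    d <- buildDesign(toyPhenotypes(4L), toyPed(4L)),
    "gender"), "parity")
  expect_equal(d$nBlocks, 1L)
  expect_equal(unname(colSums(d$Fmat > 0)), 4L)

  ## covariate assignment per trait, centered at the sample mean
  ph <- smallSim()$phenotypes
  des <- smallDesign()
  expect_equal(des$covX[, "ADFI"], ph$start_bw - mean(ph$start_bw),
               ignore_attr = TRUE)
  expect_equal(des$covX[, "ADG"], ph$start_bw - mean(ph$start_bw),
               ignore_attr = TRUE)
  expect_equal(des$covX[, "LMP"], ph$end_bw - mean(ph$end_bw),
               ignore_attr = TRUE)

  ## pen incidence: each pen's column count equals its occupancy
  expect_equal(unname(tabulate(des$penIdx, des$nPen)),
               unname(as.integer(table(ph$pen)[des$penIds])))

  ## a full pen of 12 in one pen
  set.seed(2)
  d12 <- suppressWarnings(buildDesign(toyPhenotypes(12L, pens = 1L),
                                      toyPed(12L)))
  expect_equal(sum(d12$penIdx == 1L), 12L)

  ## errors: missing animal, duplicate record, degenerate trait
  bad <- smallSim()$phenotypes
  bad$animal[1L] <- "GHOST"
  expect_error(buildDesign(bad, smallSim()$pedigree), "GHOST")
  dup <- rbind(ph, ph[1L, ])
  expect_error(buildDesign(dup, smallSim()$pedigree), "one record")
  const <- ph
  const$adfi <- 2.61
  expect_error(buildDesign(const, smallSim()$pedigree), "degenerate")
})

test_that("sampler guards reject unusable configurations", {
  des <- smallDesign()
  expect_error(runGibbs(des, nIter = 100L, burnIn = 100L), "exceed")
  tr <- defaultTruth()
  notSPD <- tr$G0
  notSPD[1L, 2L] <- notSPD[2L, 1L] <- 10
  expect_error(runGibbs(des, nIter = 200L, burnIn = 50L,
                        fixCovariances = list(G0 = notSPD, K0 = tr$K0,
                                              R0 = tr$R0)),
               "positive definite")
})

test_that("chains are bit-identical under a fixed seed", {
  des <- smallDesign()
  c1 <- runGibbs(des, nIter = 400L, burnIn = 100L, thin = 3L, seed = 7L)
  c2 <- runGibbs(des, nIter = 400L, burnIn = 100L, thin = 3L, seed = 7L)
  expect_identical(c1@G0, c2@G0)
  expect_identical(c1@additive, c2@additive)
  expect_identical(c1@fixed, c2@fixed)
  c3 <- runGibbs(des, nIter = 400L, burnIn = 100L, thin = 3L, seed = 8L)
  expect_false(identical(c1@G0, c3@G0))
  ## saved-sample count is ceiling((nIter - burnIn) / thin)
  expect_equal(nSamples(c1), ceiling((400L - 100L) / 3L))
})

test_that("every saved covariance sample is SPD, including P0", {
  ch <- smallChain()
  for (i in seq_len(nSamples(ch))) {
    cs <- covarianceSample(ch, i)
    for (M in list(cs$G0, cs$K0, cs$R0, cs$G0 + cs$K0 + cs$R0)) {
      expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("with fixed covariances the posterior mean solves the MME", {
  ## deterministic sparse-solve oracle vs the sampler, small data
  sim <- smallSim()
  des <- smallDesign()
  tr <- defaultTruth()
  ch <- runGibbs(des, nIter = 6000L, burnIn = 1000L, thin = 1L, seed = 3L,
                 fixCovariances = list(G0 = tr$G0, K0 = tr$K0, R0 = tr$R0),
                 storeResiduals = FALSE)
  mme <- mmeSolution(des, tr$G0, tr$K0, tr$R0)
  pm <- apply(ch@additive, c(1L, 2L), mean)
  for (t in 1:3) expect_gt(cor(pm[, t], mme$additive[, t]), 0.995)
  ## location effects agree within Monte-Carlo error (3 SE)
  m <- nSamples(ch)
  for (b in seq_len(dim(ch@fixed)[2L])) {
    for (t in 1:3) {
      draws <- ch@fixed[, b, t]
      se <- sd(draws) / sqrt(max(effectiveSize(draws), 1))
      expect_lt(abs(mean(draws) - mme$fixed[b, t]), 3 * se + 1e-8)
    }
  }
})

test_that("near-zero genetic signal yields near-zero heritability", {
  tr <- defaultTruth()
  tiny <- tr
  tiny$G0 <- tr$G0 * 1e-4
  tiny$K0 <- tr$K0 * 1e-4
  ## the h2 posterior under the flat covariance prior concentrates near
  ## zero only with enough records; use a mid-sized population
  cfg <- simConfig(nFounders = 300L, nGenerations = 3L,
                   matingsPerGeneration = 50L, offspringPerMating = 10L,
                   propMale = 0.5, selection = NULL)
  cfg$truth <- tiny
  sim <- simulatePopulation(cfg, seed = 5L)
  ch <- runGibbs(sim$phenotypes, sim$pedigree, nIter = 24000L,
                 burnIn = 8000L, thin = 10L, seed = 6L,
                 storeResiduals = FALSE)
  expect_lt(mean(heritability(ch, "ADFI")), 0.05)
  expect_lt(mean(heritability(ch, "ADG")), 0.05)
})

test_that("heritability arithmetic and the pen-variance option", {
  s <- list(G0 = diag(c(1, 1, 1)), K0 = diag(c(1, 0, 0)),
            R0 = diag(c(2, 1, 1)))
  expect_equal(heritability(s, 1L), 0.25)
  expect_equal(heritability(s, 1L, includePen = FALSE), 1 / 3)
  s2 <- list(G0 = diag(3), K0 = diag(0, 3L), R0 = diag(3))
  expect_equal(heritability(s2, 2L), 0.5)
})
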