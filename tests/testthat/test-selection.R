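test_that("genetic trends are per-batch means", {
  b1 <- trendBasis(rep(2008L, 3L))
  expect_equal(unname(geneticTrend(c(1, 2, 3), b1)), 2)

  b2 <- trendBasis(c(2008L, 2008L, 2009L, 2009L))
  expect_equal(unname(geneticTrend(c(0, 0, 4, 6), b2)), c(0, 5))

  set.seed(11)
  yrs <- sample(2008:2012, 60L, replace = TRUE)
  a <- rnorm(60L)
  expect_equal(unname(geneticTrend(a, trendBasis(yrs))),
               as.numeric(tapply(a, yrs, mean)[as.character(sort(unique(yrs)))]))

  expect_error(geneticTrend(1:3, b2), "different animals")
})

test_that("detrending zeroes batch means and ignores batch shifts", {
  b <- trendBasis(c(2008L, 2008L, 2009L, 2009L, 2009L))
  expect_equal(detrend(rep(5, 5L), b), rep(0, 5L))
  set.seed(12)
  a <- rnorm(5L)
  astar <- detrend(a, b)
  expect_lt(max(abs(tapply(astar, b$batch, mean))), 1e-12)
  shifted <- a + c(10, 10, -3, -3, -3)
  expect_equal(detrend(shifted, b), astar)
})

test_that("available genetic covariance collapses and degenerates correctly", {
  der <- smallDerived()
  remake <- function(idx, years = der@birthYear[idx]) {
    new("DerivedChain", values = der@values[idx, , , drop = FALSE],
        traits = der@traits, geneticCov = der@geneticCov,
        phenotypicCov = der@phenotypicCov, mu = der@mu,
        animalIds = paste0("C", seq_along(idx)), birthYear = years)
  }
  ## identical breeding values give a zero matrix
  av0 <- availableGeneticCovariance(remake(rep(1L, 5L),
                                           years = rep(2009L, 5L)))
  expect_lt(max(abs(av0)), 1e-20)

  ## a single batch equals the plain covariance of the breeding values
  one <- remake(seq_along(der@animalIds),
                years = rep(2009L, length(der@animalIds)))
  av1 <- availableGeneticCovariance(one)
  i <- 2L
  expect_equal(av1[i, , ], stats::cov(der@values[, , i]),
               ignore_attr = TRUE)

  expect_error(availableGeneticCovariance(remake(1:2)), "at least 3")
})

test_that("selected-group superiority matches brute-force enumeration", {
  ## 10 animals with breeding values 1..10, top 20% maximized
  astar <- cbind(X = 1:10)
  rownames(astar) <- sprintf("A%02d", 1:10)
  s <- selectedSuperiority(astar, "X", fraction = 0.2, direction = "max")
  expect_equal(unname(s), (10 + 9) / 2 - 5.5)

  ## all equal: zero; whole population: zero
  eq <- cbind(X = rep(2, 8L))
  expect_equal(unname(selectedSuperiority(eq, "X", 0.25, "max")), 0)
  expect_equal(unname(selectedSuperiority(astar, "X", 1.0, "max")), 0)

  ## random multi-trait values vs the oracle, both directions
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(rnorm(40L * 3L), 40L,
                dimnames = list(sprintf("B%02d", 1:40), c("u", "v", "w")))
    for (dir in c("min", "max")) {
      frac <- sample(c(0.05, 0.1, 0.25), 1L)
      expect_equal(selectedSuperiority(m, "v", frac, dir),
                   bruteForceSuperiority(m, "v", frac, dir))
    }
  }

  ## ties at the truncation boundary resolved by ascending id
  tie <- cbind(X = c(1, 2, 2, 5))
  rownames(tie) <- c("d", "c", "a", "b")
  sel <- selectedSuperiority(tie, "X", 0.5, "max")
  ## top 2 maximizing: 5 ("b") then tie 2/2 broken by id -> "a"
  expect_equal(unname(sel), mean(c(5, 2)) - mean(tie))
})

test_that("response matrices have favorable direct signs and sane shape", {
  der <- smallDerived()
  rm_ <- responseMatrix(der, fraction = 0.10)
  expect_equal(dim(rm_$mean), c(6L, 6L))
  expect_equal(nrow(rm_$table), 36L)
  ## direct superiorities carry the favorable sign in every sample
  for (tr in der@traits) {
    dir <- rm_$directions[[tr]]
    draws <- rm_$samples[, tr, tr]
    if (dir == "min") expect_true(all(draws <= 0)) else
      expect_true(all(draws >= 0))
  }
})

test_that("direct response magnitude shrinks as the fraction grows", {
  der <- smallDerived()
  basis <- trendBasis(der@birthYear)
  set.seed(31)
  samples <- sample(nSamples(der), 25L)
  for (i in samples) {
    astar <- apply(der@values[, , i], 2L, detrend, basis = basis)
    rownames(astar) <- der@animalIds
    for (tr in c("RFI_G", "FCR", "ADG")) {
      dir <- if (tr == "ADG") "max" else "min"
      mags <- sapply(c(0.05, 0.10, 0.20, 0.30), function(f)
        abs(selectedSuperiority(astar, tr, f, dir)[[tr]]))
      expect_true(all(diff(mags) <= 1e-12))
    }
  }
})

test_that("detrending is inert when the population has no genetic trend", {
  cfg <- smallConfig(selection = NULL)
  sim <- simulatePopulation(cfg, seed = 77L)
  ch <- runGibbs(sim$phenotypes, sim$pedigree, nIter = 2500L, burnIn = 500L,
                 thin = 10L, seed = 78L, storeResiduals = FALSE)
  der <- deriveTraits(ch)
  with_ <- responseMatrix(der, fraction = 0.10, detrendValues = TRUE)
  without <- responseMatrix(der, fraction = 0.10, detrendValues = FALSE)
  for (tr in der@traits) {
    diffs <- abs(with_$mean[tr, tr] - without$mean[tr, tr])
    expect_lt(diffs, with_$sd[tr, tr] + 0.02 * abs(with_$mean[tr, tr]))
  }
})
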