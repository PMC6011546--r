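test_that("partial regression solves the production sub-block", {
  ## zero covariances with ADFI give zero coefficients
  d <- diag(c(0.1, 0.01, 3))
  dimnames(d) <- list(c("ADFI", "ADG", "LMP"), c("ADFI", "ADG", "LMP"))
  expect_equal(unname(partialRegression(d, "genetic")$coefficients), c(0, 0))

  ## univariate limit: LMP independent, coefficient on ADG = cov / var
  M <- d
  M["ADFI", "ADG"] <- M["ADG", "ADFI"] <- 0.02
  b <- partialRegression(M, "phenotypic")
  expect_equal(unname(b$coefficients), c(0.02 / 0.01, 0))
  expect_equal(b$basis, "phenotypic")

  ## reference genetic variances and correlations: hand-eliminated system
  bG <- partialRegression(tableG0(), "genetic")
  expect_equal(unname(bG$coefficients), c(2.29583, -0.03393), tolerance = 1e-4)

  ## singular sub-block errors
  S <- matrix(1, 3L, 3L)
  expect_error(partialRegression(S), "singular")
})

test_that("transform matrix has the expected structure", {
  z <- c(0, 0)
  B0 <- transformMatrix(z, z)
  expect_equal(dim(B0), c(5L, 3L))
  expect_equal(unname(B0[1L, ]), c(1, 0, 0))
  expect_equal(B0[2L, ], B0[1L, ], ignore_attr = TRUE)
  expect_equal(B0[3L, ], B0[1L, ], ignore_attr = TRUE)
  expect_equal(unname(B0[4L, ]), c(0, 1, 0))
  expect_equal(unname(B0[5L, ]), c(0, 0, 1))

  B <- transformMatrix(c(1.5, 0.1), c(2.29583, -0.03393))
  expect_equal(unname(B["RFI_G", ]), c(1, -2.29583, 0.03393))
  expect_equal(unname(B["RFI_P", ]), c(1, -1.5, -0.1))
})

test_that("derived covariances honor the zero-construction and minimality", {
  ## identity covariance with zero coefficients: derived block of ones
  B <- transformMatrix(c(0, 0), c(0, 0))
  D <- derivedCovariance(B, diag(3L))
  expect_equal(unname(diag(D)), rep(1, 5))
  expect_equal(unname(D[1:3, 1:3]), matrix(1, 3L, 3L))

  set.seed(99)
  for (rep in 1:20) {
    G <- randomCov3()
    P <- G + randomCov3()
    bG <- partialRegression(G, "genetic")
    bP <- partialRegression(P, "phenotypic")
    B <- transformMatrix(bP, bG)
    DG <- derivedCovariance(B, G)
    DP <- derivedCovariance(B, P)
    ## conditional construction zeroes the matching covariances
    expect_lt(abs(DG["RFI_G", "ADG"]), 1e-10)
    expect_lt(abs(DG["RFI_G", "LMP"]), 1e-10)
    expect_lt(abs(DP["RFI_P", "ADG"]), 1e-10)
    expect_lt(abs(DP["RFI_P", "LMP"]), 1e-10)
    ## b_G minimizes the conditional genetic variance over linear
    ## adjustments of ADFI by production
    vG <- DG["RFI_G", "RFI_G"]
    for (k in 1:100) {
      cc <- rnorm(2L, sd = 2)
      alt <- G[1L, 1L] - 2 * sum(cc * G[2:3, 1L]) +
        as.numeric(crossprod(cc, G[2:3, 2:3] %*% cc))
      expect_lte(vG, alt + 1e-12)
    }
    expect_lte(vG, DG["RFI_P", "RFI_P"] + 1e-12)
  }
})

test_that("RFI breeding values follow the conditional construction", {
  a <- rbind(c(0.1, 0.05, 1.0), c(-0.2, 0.01, -0.5))
  expect_equal(rfiBreedingValues(a, c(0, 0)), a[, 1L])
  expect_equal(rfiBreedingValues(c(0.1, 0.05, 1.0), c(2.0, -0.02)), 0.02)
})

test_that("population means weight factor levels by observations", {
  info <- list(
    traits = c("ADFI", "ADG", "LMP"),
    blocks = data.frame(factor = c("year_quarter", "gender"),
                        level = c("2008Q1", "F"), count = c(10L, 3L)),
    factorTotals = c(year_quarter = 10L, gender = 10L),
    covCenter = c(50, 50, 100), covMeans = c(50, 50, 100))
  ## single-level first factor: mu equals the intercept block
  fixed <- rbind(c(2.61, 1.12, 62.7), c(0, 0, 0))
  mu <- populationMeans(fixed, c(0, 0, 0), info)
  expect_equal(mu, c(ADFI = 2.61, ADG = 1.12))

  ## two genders, effects 0 and g with weights 0.7 / 0.3
  fixed2 <- rbind(c(2.61, 1.12, 62.7), c(-0.1, -0.04, 0.8))
  mu2 <- populationMeans(fixed2, c(0, 0, 0), info)
  expect_equal(unname(mu2["ADFI"]), 2.61 + 0.3 * (-0.1))
  expect_equal(unname(mu2["ADG"]), 1.12 + 0.3 * (-0.04))

  ## non-positive ADG mean is an error (FCR undefined)
  fixed3 <- rbind(c(2.61, -1.2, 62.7), c(0, 0, 0))
  expect_error(populationMeans(fixed3, c(0, 0, 0), info), "not positive")
})

test_that("FCR breeding values match the ratio construction", {
  mu <- c(ADFI = 2.61, ADG = 1.12)
  expect_equal(fcrBreedingValues(mu, 0, 0), 0)
  expect_equal(fcrBreedingValues(mu, 0.1, 0), 0.1 / 1.12)
  expect_equal(fcrBreedingValues(mu, 0, 0.1), 2.61 / 1.22 - 2.61 / 1.12)
  expect_error(fcrBreedingValues(mu, 0, -2, ids = "A42"), "A42")
})

test_that("FCR phenotypic deviations extend the ratio with residuals", {
  mu <- c(ADFI = 2.61, ADG = 1.12)
  expect_equal(fcrPhenotypicDeviation(mu, cbind(0, 0), cbind(0, 0)), 0)
  expect_equal(fcrPhenotypicDeviation(mu, cbind(0.1, 0), cbind(0.2, 0)),
               (2.61 + 0.3) / 1.12 - 2.61 / 1.12)
  ## reduces to the breeding-value expression when residuals vanish
  a <- cbind(rnorm(5, 0, 0.05), rnorm(5, 0, 0.02))
  expect_equal(fcrPhenotypicDeviation(mu, a, cbind(0, 0)[rep(1, 5), ]),
               fcrBreedingValues(mu, a[, 1L], a[, 2L]))
})

test_that("FCR is locally linear in the additive values", {
  mu <- c(ADFI = 2.61, ADG = 1.12)
  set.seed(7)
  aF <- rnorm(200L, 0, 0.05)
  aG <- runif(200L, -0.01, 0.01) * mu[["ADG"]]
  exact <- fcrBreedingValues(mu, aF, aG)
  linear <- aF / mu[["ADG"]] - mu[["ADFI"]] / mu[["ADG"]]^2 * aG
  expect_lt(max(abs(exact - linear) / pmax(abs(exact), 1e-3)), 0.01)
})

test_that("per-sample derivation yields coherent chains", {
  der <- smallDerived()
  ch <- smallChain()
  expect_s4_class(der, "DerivedChain")
  expect_equal(nSamples(der), nSamples(ch))
  expect_equal(dim(der@values)[1L], length(ch@info$phenotypedIdx))
  ## recorded-trait columns are the raw additive values
  i <- 3L
  expect_equal(der@values[, "ADFI", i],
               ch@additive[ch@info$phenotypedIdx, 1L, i],
               ignore_attr = TRUE)
  ## RFI columns reproduce the per-sample construction
  cs <- covarianceSample(ch, i)
  bG <- partialRegression(cs$G0, "genetic")
  a <- ch@additive[ch@info$phenotypedIdx, , i]
  expect_equal(der@values[, "RFI_G", i], rfiBreedingValues(a, bG),
               ignore_attr = TRUE)
  ## FCR column vanishes where additive values vanish
  expect_equal(fcrBreedingValues(setNames(der@mu[i, ], c("ADFI", "ADG")),
                                 0, 0), 0)
})
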