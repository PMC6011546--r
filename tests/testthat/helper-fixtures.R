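## shared fixtures, memoized so expensive fits run once per test session
.fx <- new.env(parent = emptyenv())

memoFixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

## small population: 144 phenotyped pigs in 2 generations on 60 founders
smallConfig <- function(selection = list(trait = "FCR", direction = "min",
                                         basis = "phenotype",
                                         fraction = 0.25)) {
  simConfig(nFounders = 60L, nGenerations = 2L, matingsPerGeneration = 12L,
            offspringPerMating = 6L, propMale = 0.5, selection = selection)
}

smallSim <- function() {
  memoFixture("smallSim", function() simulatePopulation(smallConfig(), seed = 101L))
}

smallDesign <- function() {
  memoFixture("smallDesign", function() {
    s <- smallSim()
    buildDesign(s$phenotypes, s$pedigree)
  })
}

smallChain <- function() {
  memoFixture("smallChain", function() {
    runGibbs(smallDesign(), nIter = 4000L, burnIn = 1000L, thin = 10L,
             seed = 42L)
  })
}

smallDerived <- function() {
  memoFixture("smallDerived", function() deriveTraits(smallChain()))
}

## study-scale population: ~2000 phenotyped pigs over 3 generations,
## fitted with the default desk-scale chain (60k iterations)
studyConfig <- function() {
  simConfig(nFounders = 400L, nGenerations = 3L,
            matingsPerGeneration = 56L, offspringPerMating = 12L)
}

studySim <- function() {
  memoFixture("studySim", function() simulatePopulation(studyConfig(), seed = 1L))
}

studyChain <- function() {
  memoFixture("studyChain", function() {
    s <- studySim()
    runGibbs(s$phenotypes, s$pedigree, nIter = 60000L, burnIn = 10000L,
             thin = 25L, seed = 2L, storeResiduals = FALSE)
  })
}

studyDerived <- function() {
  memoFixture("studyDerived", function() deriveTraits(studyChain()))
}

## genetic covariance matrix assembled from the reference genetic variances
## (0.035, 0.004, 2.024) and genetic correlations (0.82, -0.39, -0.17)
tableG0 <- function() defaultTruth()$G0

## brute-force selection oracle: rank, truncate, average
bruteForceSuperiority <- function(astar, criterion, fraction, direction,
                                  ids = rownames(astar)) {
  df <- data.frame(id = ids, crit = astar[, criterion])
  df <- df[order(if (direction == "min") df$crit else -df$crit, df$id), ]
  ns <- ceiling(fraction * nrow(df))
  sel <- match(df$id[seq_len(ns)], ids)
  colMeans(astar[sel, , drop = FALSE]) - colMeans(astar)
}

## random SPD 3x3 trait covariance with realistic scale
randomCov3 <- function() {
  L <- matrix(rnorm(9L), 3L) * 0.3 + diag(c(0.2, 0.07, 1.4))
  M <- tcrossprod(L) + diag(1e-4, 3L)
  dimnames(M) <- list(c("ADFI", "ADG", "LMP"), c("ADFI", "ADG", "LMP"))
  M
}
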