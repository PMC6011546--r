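#' Default truth parameters for the simulator
#'
#' Assembles the generating covariance matrices and means used by the
#' population simulator.  G0 comes from the genetic variances (0.035,
#' 0.004, 2.024) and genetic correlations (0.82, -0.39, -0.17) of the
#' traits ADFI, ADG and LMP; the phenotypic matrix P0 is fixed by the
#' heritabilities (0.32, 0.26, 0.56) and the phenotypic correlations
#' (0.68, -0.30, -0.17).  The non-genetic remainder P0 - G0 is split
#' 10/90 between pen (K0) and residual (R0) with a common correlation
#' structure, so K0 + R0 reproduces P0 - G0 exactly.  All three matrices
#' are verified SPD at construction.
#'
#' @param penShare share of the non-genetic (co)variance assigned to pens
#'   (default 0.10).
#' @return list with matrices \code{G0, K0, R0, P0}, trait \code{means}
#'   (ADFI 2.61 kg/d, ADG 1.12 kg/d, LMP 62.7 pct), \code{h2},
#'   covariate means/SDs (\code{sbw} 54.9/11.3 kg) and the fixed covariate
#'   regressions \code{beta} used in simulation.
#' @export
defaultTruth <- function(penShare = 0.10) {
  stopifnot(penShare > 0, penShare < 1)
  traits <- c("ADFI", "ADG", "LMP")
  h2 <- c(ADFI = 0.32, ADG = 0.26, LMP = 0.56)
  gVar <- c(ADFI = 0.035, ADG = 0.004, LMP = 2.024)
  gCor <- matrix(c(1, 0.82, -0.39,
                   0.82, 1, -0.17,
                   -0.39, -0.17, 1), 3L, 3L, dimnames = list(traits, traits))
  pCor <- matrix(c(1, 0.68, -0.30,
                   0.68, 1, -0.17,
                   -0.30, -0.17, 1), 3L, 3L, dimnames = list(traits, traits))
  gSd <- sqrt(gVar)
  G0 <- gCor * tcrossprod(gSd)
  pVar <- gVar / h2
  P0 <- pCor * tcrossprod(sqrt(pVar))
  N0 <- P0 - G0
  K0 <- penShare * N0
  R0 <- (1 - penShare) * N0
  for (M in list(G0 = G0, K0 = K0, R0 = R0)) {
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("assembled covariance matrix not SPD")
  }
  list(G0 = G0, K0 = K0, R0 = R0, P0 = P0,
       means = c(ADFI = 2.61, ADG = 1.12, LMP = 62.7),
       h2 = h2,
       sbw = c(mean = 54.9, sd = 11.3),
       daysOnTest = c(50L, 60L),
       beta = c(ADFI = 0.010, ADG = 0.002, LMP = -0.020))
}

#' Simulation configuration
#'
#' Describes a pedigreed population to simulate: an unphenotyped founder
#' herd, a fixed number of discrete offspring generations whose pigs are
#' phenotyped in mixed-sex pens, and an optional between-generation
#' truncation-selection rule that induces genetic trends.  Defaults emulate
#' a commercial test station: about 3000 phenotyped pigs (87 percent
#' boars) in pens of 12 across four generations, on top of 600 founders.
#'
#' @param nFounders unphenotyped founder animals (sex ratio 1:1).
#' @param nGenerations phenotyped offspring generations.
#' @param matingsPerGeneration litters per generation.
#' @param offspringPerMating phenotyped pigs per litter.
#' @param penSize pigs per pen (default 12).
#' @param propMale probability an offspring is male (default 2621/3027).
#' @param sireMatings litters per selected sire (default 4).
#' @param truth generating parameters, see [defaultTruth()].
#' @param selection \code{NULL} for random parent choice, or a list with
#'   \code{trait} (one of ADFI, ADG, LMP, FCR), \code{direction}
#'   ("min"/"max"), \code{basis} ("phenotype" uses recorded phenotypes,
#'   the choice compatible with unbiased inference from the recorded data;
#'   "true_bv" selects on true additive values) and \code{fraction}
#'   (eligible top fraction per sex).  Default: minimize phenotypic FCR,
#'   top 25 percent.
#' @param baseYear birth year of the founders.
#' @return object of class \code{feSimConfig}.
#' @export
simConfig <- function(nFounders = 600L, nGenerations = 4L,
                      matingsPerGeneration = 63L, offspringPerMating = 12L,
                      penSize = 12L, propMale = 2621 / 3027,
                      sireMatings = 4L, truth = defaultTruth(),
                      selection = list(trait = "FCR", direction = "min",
                                       basis = "phenotype", fraction = 0.25),
                      baseYear = 2007L) {
  stopifnot(nFounders >= 4L, nGenerations >= 1L, matingsPerGeneration >= 1L,
            offspringPerMating >= 1L, penSize >= 1L,
            propMale > 0, propMale < 1)
  if (!is.null(selection)) {
    stopifnot(selection$trait %in% c("ADFI", "ADG", "LMP", "FCR"),
              selection$direction %in% c("min", "max"),
              selection$basis %in% c("phenotype", "true_bv"),
              selection$fraction > 0, selection$fraction <= 1)
  }
  structure(list(nFounders = as.integer(nFounders),
                 nGenerations = as.integer(nGenerations),
                 matingsPerGeneration = as.integer(matingsPerGeneration),
                 offspringPerMating = as.integer(offspringPerMating),
                 penSize = as.integer(penSize), propMale = propMale,
                 sireMatings = as.integer(sireMatings),
                 truth = truth, selection = selection,
                 baseYear = as.integer(baseYear)),
            class = "feSimConfig")
}

#' @export
print.feSimConfig <- function(x, ...) {
  nOff <- x$nGenerations * x$matingsPerGeneration * x$offspringPerMating
  cat("feSimConfig:", x$nFounders, "founders +", nOff, "phenotyped pigs in",
      x$nGenerations, "generation(s), pens of", x$penSize, "\n")
  if (is.null(x$selection)) cat("  no selection between generations\n")
  else cat("  selection:", x$selection$direction, x$selection$trait, "on",
           x$selection$basis, "( top", x$selection$fraction, ")\n")
  invisible(x)
}

#' Mendelian sampling of an offspring's additive values
#'
#' \code{offspring = (sire + dam)/2 + s}, with the Mendelian sampling
#' deviation \code{s ~ N(0, (0.5 - 0.25 (F_s + F_d)) G0)}.
#'
#' @param sireA,damA length-3 additive values of the parents.
#' @param Fs,Fd parental inbreeding coefficients.
#' @param G0 3x3 additive-genetic covariance matrix.
#' @return length-3 offspring additive values.
#' @export
mendelianSample <- function(sireA, damA, Fs, Fd, G0) {
  v <- 0.5 - 0.25 * (Fs + Fd)
  dev <- if (v > 0) {
    as.numeric(crossprod(.cholSafe(G0), rnorm(3L))) * sqrt(v)
  } else {
    numeric(3L)
  }
  0.5 * (sireA + damA) + dev
}

## upper Cholesky factor, tolerating the all-zero (no-variance) limit
.cholSafe <- function(M) {
  M <- unname(as.matrix(M))
  if (max(abs(M)) == 0) M else chol(M)
}

## deterministic "true" fixed-effect tables, independent of the user seed
.fixedEffectTable <- function(levels, means, spread, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- sapply(means, function(m) runif(length(levels), -spread, spread) * m)
  rownames(out) <- levels
  out
}

#' Simulate a pedigreed population with phenotypes
#'
#' Generates a founder herd and \code{nGenerations} phenotyped offspring
#' generations under the trivariate model: phenotype = year-quarter +
#' gender + parity + covariate regression + additive + pen + residual.
#' Founder additive values are drawn from G0; offspring values are the
#' parent average plus an inbreeding-adjusted Mendelian sampling deviation
#' ([mendelianSample()]), so the stacked additive values realize
#' \code{A (x) G0}.  Between generations, parents are chosen per the
#' configured selection rule, inducing genetic trends.
#'
#' @param config an \code{feSimConfig} from [simConfig()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with \code{pedigree} (a [Pedigree-class]),
#'   \code{phenotypes} (data.frame, one row per phenotyped pig) and
#'   \code{truth} (true additive values per pedigree animal, true pen
#'   effects, true residuals, the generating parameters).
#' @export
simulatePopulation <- function(config = simConfig(), seed = 1L) {
  stopifnot(inherits(config, "feSimConfig"))
  set.seed(seed)
  tr <- config$truth
  G0 <- unname(tr$G0)
  cholG <- .cholSafe(G0)
  nF <- config$nFounders
  nGen <- config$nGenerations
  nMat <- config$matingsPerGeneration
  nOff <- config$offspringPerMating
  qTot <- nF + nGen * nMat * nOff

  id <- sprintf("A%05d", seq_len(qTot))
  sire <- integer(qTot)
  dam <- integer(qTot)
  year <- integer(qTot)
  sex <- character(qTot)      # "M"/"F"
  aTrue <- matrix(NA_real_, qTot, 3L)

  ## founders: parental herd, unphenotyped, balanced sexes
  year[seq_len(nF)] <- config$baseYear
  sex[seq_len(nF)] <- rep_len(c("M", "F"), nF)
  aTrue[seq_len(nF), ] <- matrix(rnorm(3L * nF), nF, 3L) %*% cholG

  ## deterministic truth tables for the fixed effects
  yqLevels <- as.vector(outer(1:4, config$baseYear + seq_len(nGen),
                              function(q, y) paste0(y, "Q", q)))
  yqEff <- .fixedEffectTable(yqLevels, tr$means, 0.05, 104729L)
  parEff <- .fixedEffectTable(as.character(1:6), tr$means, 0.02, 224737L)
  genderEff <- rbind(M = c(0, 0, 0), F = c(-0.08, -0.04, 0.8))

  phen <- vector("list", nGen)
  penCount <- 0L
  F <- numeric(qTot)  # inbreeding, grown generation by generation
  done <- nF

  rank1 <- function(values, direction) {
    order(if (direction == "min") values else -values)
  }
  resample <- function(x, n) x[sample.int(length(x), n)]

  for (g in seq_len(nGen)) {
    prevIdx <- if (g == 1L) seq_len(nF)
               else (done - nMat * nOff + 1L):done
    males <- prevIdx[sex[prevIdx] == "M"]
    females <- prevIdx[sex[prevIdx] == "F"]
    nSires <- max(1L, ceiling(nMat / config$sireMatings))
    if (length(males) < nSires || length(females) < nMat) {
      stop("population extinct in generation ", g, ": need ", nSires,
           " sires and ", nMat, " dams, have ", length(males), "/",
           length(females))
    }
    sel <- config$selection
    pickTop <- function(cand, nNeed) {
      ## founders carry no phenotype, so phenotypic rules start in
      ## generation 2; true-BV rules can select founders as well
      if (is.null(sel) || (g == 1L && sel$basis == "phenotype")) {
        return(resample(cand, nNeed))
      }
      val <- if (sel$basis == "true_bv") {
        switch(sel$trait,
               FCR = (tr$means[1L] + aTrue[cand, 1L]) /
                     (tr$means[2L] + aTrue[cand, 2L]),
               aTrue[cand, match(sel$trait, c("ADFI", "ADG", "LMP"))])
      } else {
        ph <- phen[[g - 1L]]
        rows <- match(id[cand], ph$animal)
        switch(sel$trait,
               FCR = ph$adfi[rows] / ph$adg[rows],
               ADFI = ph$adfi[rows], ADG = ph$adg[rows], LMP = ph$lmp[rows])
      }
      pool <- cand[rank1(val, sel$direction)]
      nPool <- max(nNeed, ceiling(sel$fraction * length(cand)))
      eligible <- pool[seq_len(min(nPool, length(pool)))]
      if (length(eligible) > nNeed) resample(eligible, nNeed)
      else eligible
    }
    sires <- pickTop(males, nSires)
    dams <- pickTop(females, nMat)
    matingSire <- resample(rep_len(sires, nMat), nMat)

    ## inbreeding of all animals so far (parents of this generation)
    pedSoFar <- new("Pedigree", id = id[seq_len(done)],
                    sire = sire[seq_len(done)], dam = dam[seq_len(done)],
                    birthYear = year[seq_len(done)])
    F[seq_len(done)] <- inbreedingCoefficients(pedSoFar)

    newIdx <- done + seq_len(nMat * nOff)
    litter <- rep(seq_len(nMat), each = nOff)
    sire[newIdx] <- matingSire[litter]
    dam[newIdx] <- dams[litter]
    year[newIdx] <- config$baseYear + g
    sex[newIdx] <- ifelse(runif(length(newIdx)) < config$propMale, "M", "F")
    ms <- 0.5 - 0.25 * (F[sire[newIdx]] + F[dam[newIdx]])
    dev <- (matrix(rnorm(3L * length(newIdx)), ncol = 3L) %*% cholG) *
      sqrt(pmax(ms, 0))
    aTrue[newIdx, ] <- 0.5 * (aTrue[sire[newIdx], , drop = FALSE] +
                              aTrue[dam[newIdx], , drop = FALSE]) + dev

    ## pens of penSize within the generation; pen-mates share a quarter
    nNew <- length(newIdx)
    shuffled <- resample(newIdx, nNew)
    penOf <- ceiling(seq_len(nNew) / config$penSize)
    nPens <- max(penOf)
    penId <- sprintf("P%04d", penCount + penOf)
    penCount <- penCount + nPens
    penQuarter <- sample(1:4, nPens, replace = TRUE)
    penEff <- matrix(rnorm(3L * nPens), nPens, 3L) %*% .cholSafe(tr$K0)
    eEff <- matrix(rnorm(3L * nNew), nNew, 3L) %*% .cholSafe(tr$R0)
    parity <- sample(1:6, nMat, replace = TRUE)

    ord <- match(newIdx, shuffled)   # pen assignment of each new animal
    penIdxAni <- penOf[ord]
    yq <- paste0(year[newIdx], "Q", penQuarter[penIdxAni])
    sbw <- tr$sbw["mean"] + tr$sbw["sd"] * rnorm(nNew)
    sbw <- pmax(sbw, 20)
    days <- sample(tr$daysOnTest[1L]:tr$daysOnTest[2L], nNew, replace = TRUE)
    gEff <- genderEff[sex[newIdx], , drop = FALSE]
    pEff <- parEff[as.character(parity[litter]), , drop = FALSE]
    yEff <- yqEff[yq, , drop = FALSE]
    aNew <- aTrue[newIdx, , drop = FALSE]
    pen3 <- penEff[penIdxAni, , drop = FALSE]
    eAni <- eEff[ord, , drop = FALSE]

    ebwRef <- tr$sbw["mean"] + mean(tr$daysOnTest) * tr$means["ADG"]
    adfi <- tr$means["ADFI"] + yEff[, 1L] + gEff[, 1L] + pEff[, 1L] +
      tr$beta["ADFI"] * (sbw - tr$sbw["mean"]) +
      aNew[, 1L] + pen3[, 1L] + eAni[, 1L]
    adg <- tr$means["ADG"] + yEff[, 2L] + gEff[, 2L] + pEff[, 2L] +
      tr$beta["ADG"] * (sbw - tr$sbw["mean"]) +
      aNew[, 2L] + pen3[, 2L] + eAni[, 2L]
    ebw <- sbw + days * adg
    lmp <- tr$means["LMP"] + yEff[, 3L] + gEff[, 3L] + pEff[, 3L] +
      tr$beta["LMP"] * (ebw - ebwRef) +
      aNew[, 3L] + pen3[, 3L] + eAni[, 3L]

    phen[[g]] <- data.frame(
      animal = id[newIdx], pen = penId[ord], year_quarter = yq,
      gender = sex[newIdx], parity = parity[litter],
      start_bw = as.numeric(sbw), end_bw = as.numeric(ebw),
      adfi = as.numeric(adfi), adg = as.numeric(adg),
      lmp = as.numeric(lmp),
      residual_adfi = eAni[, 1L], residual_adg = eAni[, 2L],
      residual_lmp = eAni[, 3L],
      pen_adfi = pen3[, 1L], pen_adg = pen3[, 2L], pen_lmp = pen3[, 3L],
      stringsAsFactors = FALSE)
    done <- done + nNew
  }

  ped <- new("Pedigree", id = id, sire = sire, dam = dam, birthYear = year)
  validObject(ped)
  phenotypes <- do.call(rbind, phen)
  truthA <- aTrue
  dimnames(truthA) <- list(id, c("ADFI", "ADG", "LMP"))
  keep <- c("animal", "pen", "year_quarter", "gender", "parity",
            "start_bw", "end_bw", "adfi", "adg", "lmp")
  list(pedigree = ped,
       phenotypes = phenotypes[, keep],
       truth = list(additive = truthA, sex = setNames(sex, id),
                    residuals = phenotypes[, c("animal", "residual_adfi",
                                               "residual_adg",
                                               "residual_lmp")],
                    penEffects = phenotypes[, c("animal", "pen_adfi",
                                                "pen_adg", "pen_lmp")],
                    params = tr))
}
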