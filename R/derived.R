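#' Partial regression coefficients of feed intake on production
#'
#' Solves the 2x2 system of the (ADG, LMP) sub-block of a 3x3 trait
#' covariance matrix against the covariances of those traits with ADFI:
#' \code{b = C[p,p]^{-1} C[p,ADFI]} with \code{p = (ADG, LMP)}.  Applied to
#' the genetic covariance matrix this gives the genetic coefficients
#' \code{b_G} (basis "genetic"); applied to the phenotypic matrix
#' P0 = G0 + K0 + R0 it gives \code{b_P}.
#'
#' @param cov3 SPD 3x3 covariance matrix, trait order (ADFI, ADG, LMP).
#' @param basis "genetic" or "phenotypic" (a label carried along).
#' @return object of class \code{fePartialRegression}: list with
#'   \code{coefficients} (named: ADG in kg feed per kg gain, LMP in kg feed
#'   per percent lean) and \code{basis}.
#' @examples
#' G0 <- defaultTruth()$G0
#' partialRegression(G0, "genetic")
#' @export
partialRegression <- function(cov3, basis = c("genetic", "phenotypic")) {
  basis <- match.arg(basis)
  cov3 <- as.matrix(cov3)
  stopifnot(identical(dim(cov3), c(3L, 3L)))
  sub <- cov3[2:3, 2:3]
  if (abs(det(sub)) < .Machine$double.eps * max(abs(sub))^2 * 4) {
    stop("singular (ADG, LMP) covariance sub-block")
  }
  b <- solve(sub, cov3[2:3, 1L])
  structure(list(coefficients = setNames(as.numeric(b), c("ADG", "LMP")),
                 basis = basis),
            class = "fePartialRegression")
}

#' @export
print.fePartialRegression <- function(x, ...) {
  cat("partial", x$basis, "regression of ADFI on (ADG, LMP):\n")
  print(x$coefficients)
  invisible(x)
}

#' Transform matrix from recorded to derived traits
#'
#' The 5x3 matrix B mapping (ADFI, ADG, LMP) to
#' (ADFI, RFI_P, RFI_G, ADG, LMP): row 1 is (1,0,0), rows 2 and 3 are
#' (1, -b_ADG, -b_LMP) with the phenotypic and genetic coefficients
#' respectively, rows 4-5 are identity rows.
#'
#' @param bP,bG \code{fePartialRegression} objects (or bare length-2
#'   coefficient vectors) on the phenotypic and genetic basis.
#' @return 5x3 numeric matrix with rownames
#'   \code{c("ADFI","RFI_P","RFI_G","ADG","LMP")}.
#' @export
transformMatrix <- function(bP, bG) {
  cf <- function(b) if (inherits(b, "fePartialRegression")) b$coefficients
                    else as.numeric(b)
  p <- cf(bP); g <- cf(bG)
  stopifnot(length(p) == 2L, length(g) == 2L)
  B <- rbind(ADFI  = c(1, 0, 0),
             RFI_P = c(1, -p[1L], -p[2L]),
             RFI_G = c(1, -g[1L], -g[2L]),
             ADG   = c(0, 1, 0),
             LMP   = c(0, 0, 1))
  colnames(B) <- c("ADFI", "ADG", "LMP")
  B
}

#' Covariances of recorded and derived traits
#'
#' Congruence transform \code{B cov3 B'}.  With the genetic covariance
#' matrix this yields the 5x5 genetic (co)variances of (ADFI, RFI_P, RFI_G,
#' ADG, LMP); by construction the (RFI_G, ADG) and (RFI_G, LMP) genetic
#' covariances are zero.  With the phenotypic matrix P0 the (RFI_P, ADG) and
#' (RFI_P, LMP) phenotypic covariances are zero.
#'
#' @param B 5x3 matrix from [transformMatrix()].
#' @param cov3 3x3 covariance matrix (genetic or phenotypic basis).
#' @return 5x5 symmetric matrix.
#' @export
derivedCovariance <- function(B, cov3) {
  out <- B %*% as.matrix(cov3) %*% t(B)
  (out + t(out)) / 2
}

#' RFI additive values from one posterior sample
#'
#' \code{a_RFI = a_ADFI - (a_ADG, a_LMP) b}, with \code{b} the partial
#' regression coefficients drawn from the same posterior sample as the
#' additive values.
#'
#' @param a numeric matrix (animals x 3) of additive values, trait order
#'   (ADFI, ADG, LMP); a bare length-3 vector is treated as one animal.
#' @param b an \code{fePartialRegression} (or length-2 coefficient vector).
#' @return numeric vector of per-animal RFI additive values (kg/d).
#' @export
rfiBreedingValues <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  cf <- if (inherits(b, "fePartialRegression")) b$coefficients
        else as.numeric(b)
  as.numeric(a[, 1L] - a[, 2:3, drop = FALSE] %*% cf)
}

#' Population means of ADFI and ADG from one posterior sample
#'
#' Builds the per-sample population mean of each trait from the "fixed"
#' location parameters: the observation-weighted mean of each factor's
#' level effects (corner-constrained reference levels contribute zero),
#' plus the covariate regression evaluated at the population-average
#' covariate.  Computed once per sample, so the uncertainty of the mean
#' propagates into the FCR breeding values.
#'
#' @param fixed numeric matrix (nBlocks x 3) of factor-level effects of one
#'   sample.
#' @param betaCov length-3 covariate regressions of the same sample.
#' @param info design description (the \code{info} slot of a
#'   [GibbsChain-class]).
#' @return named numeric vector \code{c(ADFI =, ADG =)}; errors if the ADG
#'   mean is not strictly positive (the FCR ratio is then undefined).
#' @export
populationMeans <- function(fixed, betaCov, info) {
  mu <- numeric(3L)
  N <- info$factorTotals
  for (t in 1:3) {
    contrib <- sum(fixed[, t] * info$blocks$count /
                     N[info$blocks$factor])
    mu[t] <- contrib + betaCov[t] * (info$covMeans[t] - info$covCenter[t])
  }
  names(mu) <- info$traits
  if (mu[2L] <= 0) {
    stop("population mean of ADG is not positive (", format(mu[2L]),
         "); FCR is undefined for this sample")
  }
  mu[1:2]
}

#' FCR breeding values
#'
#' Additive deviation of the feed conversion ratio, defined through the
#' ratio of the component traits at the population mean:
#' \code{a_FCR = (mu_ADFI + a_ADFI)/(mu_ADG + a_ADG) - mu_ADFI/mu_ADG}.
#' Zero additive values map to exactly zero.
#'
#' @param mu named vector with ADFI and ADG population means of the sample.
#' @param aADFI,aADG per-animal additive values for ADFI and ADG.
#' @param ids optional animal ids for error reporting.
#' @param sample optional sample index for error reporting.
#' @return numeric vector of per-animal FCR additive deviations (kg/kg).
#' @export
fcrBreedingValues <- function(mu, aADFI, aADG, ids = NULL, sample = NULL) {
  den <- mu[["ADG"]] + aADG
  if (any(den <= 0)) {
    bad <- which(den <= 0)
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("ADG denominator not positive for animal(s) ", lab,
         if (!is.null(sample)) paste0(" in sample ", sample) else "")
  }
  (mu[["ADFI"]] + aADFI) / den - mu[["ADFI"]] / mu[["ADG"]]
}

#' FCR phenotypic deviations
#'
#' Like [fcrBreedingValues()] with the residuals of the component traits
#' added to numerator and denominator.  This quantity cannot be used to
#' derive the phenotypic variance of FCR in the population; it serves only
#' to compare phenotypic spread of the derived traits between the recorded
#' animals available for selection.
#'
#' @param mu named vector with ADFI and ADG population means of the sample.
#' @param a animals x 2 matrix (or vectors via \code{cbind}) of additive
#'   values for (ADFI, ADG).
#' @param e animals x 2 matrix of residuals for (ADFI, ADG).
#' @inheritParams fcrBreedingValues
#' @return numeric vector of per-animal phenotypic FCR deviations (kg/kg).
#' @export
fcrPhenotypicDeviation <- function(mu, a, e, ids = NULL, sample = NULL) {
  a <- as.matrix(a); e <- as.matrix(e)
  den <- mu[["ADG"]] + a[, 2L] + e[, 2L]
  if (any(den <= 0)) {
    bad <- which(den <= 0)
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("ADG denominator not positive for animal(s) ", lab,
         if (!is.null(sample)) paste0(" in sample ", sample) else "")
  }
  (mu[["ADFI"]] + a[, 1L] + e[, 1L]) / den - mu[["ADFI"]] / mu[["ADG"]]
}

#' Derive RFI and FCR breeding values for every posterior sample
#'
#' Runs the whole per-sample derivation over a fitted chain: partial
#' regression coefficients on the genetic (from G0) and phenotypic (from
#' P0 = G0 + K0 + R0) basis, RFI_G and RFI_P additive values, population
#' means, FCR breeding values, and the 5x5 derived genetic and phenotypic
#' covariance matrices.  Everything is computed sample by sample and only
#' then summarized ("functions first, averaging last").
#'
#' @param chain a [GibbsChain-class].
#' @param animals candidate set: character ids or integer pedigree
#'   positions; default all phenotyped animals.
#' @return a [DerivedChain-class] with traits
#'   (RFI_G, RFI_P, FCR, ADFI, ADG, LMP).
#' @export
deriveTraits <- function(chain, animals = NULL) {
  stopifnot(is(chain, "GibbsChain"))
  info <- chain@info
  if (is.null(animals)) {
    idx <- info$phenotypedIdx
  } else if (is.character(animals)) {
    idx <- match(animals, info$animalIds)
    if (anyNA(idx)) stop("unknown animal id(s): ",
                         paste(animals[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(animals)
  }
  m <- nSamples(chain)
  nA <- length(idx)
  traits <- c("RFI_G", "RFI_P", "FCR", "ADFI", "ADG", "LMP")
  vals <- array(NA_real_, c(nA, 6L, m),
                dimnames = list(info$animalIds[idx], traits, NULL))
  gcov <- array(NA_real_, c(m, 5L, 5L))
  pcov <- array(NA_real_, c(m, 5L, 5L))
  mus <- matrix(NA_real_, m, 2L, dimnames = list(NULL, c("ADFI", "ADG")))
  for (i in seq_len(m)) {
    cs <- covarianceSample(chain, i)
    P0 <- cs$G0 + cs$K0 + cs$R0
    bG <- partialRegression(cs$G0, "genetic")
    bP <- partialRegression(P0, "phenotypic")
    B <- transformMatrix(bP, bG)
    gcov[i, , ] <- derivedCovariance(B, cs$G0)
    pcov[i, , ] <- derivedCovariance(B, P0)
    a <- matrix(chain@additive[idx, , i], ncol = 3L)
    mu <- populationMeans(matrix(chain@fixed[i, , ], ncol = 3L),
                          chain@betaCov[i, ], info)
    mus[i, ] <- mu
    vals[, "RFI_G", i] <- rfiBreedingValues(a, bG)
    vals[, "RFI_P", i] <- rfiBreedingValues(a, bP)
    vals[, "FCR", i] <- fcrBreedingValues(mu, a[, 1L], a[, 2L],
                                          ids = info$animalIds[idx],
                                          sample = i)
    vals[, "ADFI", i] <- a[, 1L]
    vals[, "ADG", i] <- a[, 2L]
    vals[, "LMP", i] <- a[, 3L]
  }
  dn <- list(c("ADFI", "RFI_P", "RFI_G", "ADG", "LMP"))
  dimnames(gcov) <- c(list(NULL), dn, dn)
  dimnames(pcov) <- c(list(NULL), dn, dn)
  new("DerivedChain", values = vals, traits = traits,
      geneticCov = gcov, phenotypicCov = pcov, mu = mus,
      animalIds = info$animalIds[idx],
      birthYear = info$birthYear[idx])
}

#' Posterior summary of the derived trait covariances
#'
#' Posterior means and SDs of the per-sample derived genetic (or
#' phenotypic) variances and correlations of (ADFI, RFI_P, RFI_G, ADG,
#' LMP).
#'
#' @param derived a [DerivedChain-class].
#' @param basis "genetic" or "phenotypic".
#' @return list with matrices \code{mean}, \code{sd} (covariances) and
#'   \code{corMean}, \code{corSd} (correlations).
#' @export
derivedCovarianceSummary <- function(derived,
                                     basis = c("genetic", "phenotypic")) {
  basis <- match.arg(basis)
  arr <- if (basis == "genetic") derived@geneticCov else derived@phenotypicCov
  m <- dim(arr)[1L]
  cors <- array(NA_real_, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(m)) cors[i, , ] <- stats::cov2cor(arr[i, , ])
  appl <- function(a, f) apply(a, c(2L, 3L), f)
  list(mean = appl(arr, mean), sd = appl(arr, sd),
       corMean = appl(cors, mean), corSd = appl(cors, sd))
}
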