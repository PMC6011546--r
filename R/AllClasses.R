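#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal bdiag crossprod t solve
#' @importFrom stats rnorm runif var sd cor acf quantile pnorm setNames
#' @importFrom utils head tail
#' @useDynLib BayesFeedEff, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Pedigree of an animal population
#'
#' Stores animal identifiers, parent links (as positions into the pedigree,
#' \code{0L} meaning unknown) and birth years, in topological order: every
#' known parent precedes its offspring.  Construct with [pedigree()] or
#' [readPedigree()]; the raw slots are not part of the API.
#'
#' @slot id character vector of unique animal identifiers.
#' @slot sire,dam integer positions of the parents in \code{id} (\code{0L} =
#'   unknown).
#' @slot birthYear integer birth year per animal (\code{NA} allowed for
#'   implicitly added founders).
#'
#' @seealso [relationshipMatrix()], [inbreedingCoefficients()], [aInverse()]
#' @export
setClass("Pedigree",
  slots = c(id = "character", sire = "integer", dam = "integer",
            birthYear = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (anyDuplicated(object@id)) return("duplicate animal ids")
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@birthYear) != n)
    return("slot lengths differ")
  bad <- which(object@sire >= seq_len(n) | object@dam >= seq_len(n))
  if (length(bad))
    return(paste0("parent does not precede offspring for: ",
                  paste(object@id[head(bad, 5L)], collapse = ", ")))
  if (any(object@sire < 0L) || any(object@dam < 0L))
    return("negative parent index")
  TRUE
})

#' Posterior chain from the trivariate Gibbs sampler
#'
#' Thinned post-burn-in samples of all model unknowns of the trivariate
#' animal model: the additive-genetic (\code{G0}), pen (\code{K0}) and
#' residual (\code{R0}) 3x3 covariance matrices, all "fixed" location
#' effects, covariate regressions, and the per-animal additive values for
#' ADFI, ADG and LMP (and optionally the residuals of the phenotyped
#' animals).  Produced by [runGibbs()]; summarized with [summarizeChain()];
#' consumed by [deriveTraits()].
#'
#' @slot G0,K0,R0 numeric arrays \code{m x 3 x 3} of covariance samples.
#' @slot fixed numeric array \code{m x nBlock x 3} of factor-level effects
#'   (corner-constrained reference levels are identically zero and are not
#'   stored as blocks).
#' @slot betaCov numeric matrix \code{m x 3} of covariate regressions
#'   (on centered start body weight for ADFI and ADG, centered end body
#'   weight for LMP).
#' @slot additive numeric array \code{q x 3 x m}, additive values for every
#'   pedigree animal.
#' @slot residuals numeric array \code{n x 3 x m} (or 0-extent if not
#'   stored), residuals of the phenotyped animals.
#' @slot info list describing the design: factor levels and observation
#'   counts, covariate centers and means, animal ids, birth years, the
#'   phenotyped subset, pen ids, trait names.
#' @slot meta list with \code{nIter}, \code{burnIn}, \code{thin},
#'   \code{seed}, and whether covariances were held fixed.
#' @export
setClass("GibbsChain",
  slots = c(G0 = "array", K0 = "array", R0 = "array",
            fixed = "array", betaCov = "matrix",
            additive = "array", residuals = "array",
            info = "list", meta = "list"))

setValidity("GibbsChain", function(object) {
  m <- dim(object@G0)[1L]
  if (!identical(dim(object@G0), dim(object@K0)) ||
      !identical(dim(object@G0), dim(object@R0)))
    return("covariance sample arrays differ in shape")
  if (dim(object@G0)[2L] != 3L || dim(object@G0)[3L] != 3L)
    return("covariance samples must be 3x3")
  if (nrow(object@betaCov) != m || dim(object@fixed)[1L] != m)
    return("location-sample arrays disagree with number of samples")
  if (dim(object@additive)[3L] != m)
    return("additive sample array disagrees with number of samples")
  TRUE
})

#' Per-sample breeding values for recorded and derived traits
#'
#' Breeding values of the selection candidates for the six traits of
#' interest -- RFI_G, RFI_P, FCR, ADFI, ADG and LMP -- computed per posterior
#' sample ("functions first, averaging last"), together with the per-sample
#' 5x5 derived genetic and phenotypic covariance matrices.  Produced by
#' [deriveTraits()]; consumed by [responseMatrix()],
#' [availableGeneticCovariance()] and [geneticTrend()].
#'
#' @slot values numeric array \code{nAnimal x 6 x m}.
#' @slot traits character(6), trait order of \code{values}.
#' @slot geneticCov,phenotypicCov numeric arrays \code{m x 5 x 5}; the
#'   congruence transforms \code{B G0 B'} and \code{B P0 B'} per sample,
#'   rows/cols ordered (ADFI, RFI_P, RFI_G, ADG, LMP).
#' @slot mu numeric matrix \code{m x 2}, per-sample population means of
#'   ADFI and ADG used in the FCR construction.
#' @slot animalIds,birthYear id and birth year of each candidate.
#' @export
setClass("DerivedChain",
  slots = c(values = "array", traits = "character",
            geneticCov = "array", phenotypicCov = "array",
            mu = "matrix", animalIds = "character", birthYear = "integer"))

setValidity("DerivedChain", function(object) {
  d <- dim(object@values)
  if (d[2L] != length(object@traits)) return("trait dimension mismatch")
  if (d[1L] != length(object@animalIds)) return("animal dimension mismatch")
  if (dim(object@geneticCov)[1L] != d[3L]) return("sample dimension mismatch")
  TRUE
})

#' @describeIn Pedigree number of animals
#' @param x a \code{Pedigree}
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(object@sire == 0L & object@dam == 0L)
  yr <- range(object@birthYear, na.rm = TRUE)
  cat("Pedigree with", n, "animals (", founders, "founders ),",
      "birth years", yr[1L], "-", yr[2L], "\n")
})

setMethod("show", "GibbsChain", function(object) {
  m <- dim(object@G0)[1L]
  cat("GibbsChain:", m, "saved samples of the trivariate animal model\n")
  cat("  traits:", paste(object@info$traits, collapse = ", "), "\n")
  cat("  animals in pedigree:", dim(object@additive)[1L],
      "| phenotyped:", length(object@info$phenotypedIdx), "\n")
  cat("  iterations:", object@meta$nIter, "burn-in:", object@meta$burnIn,
      "thin:", object@meta$thin, "seed:", object@meta$seed, "\n")
  if (isTRUE(object@meta$fixedCovariances))
    cat("  covariance matrices held fixed (validation mode)\n")
})

setMethod("show", "DerivedChain", function(object) {
  d <- dim(object@values)
  cat("DerivedChain:", d[3L], "samples x", d[1L], "candidates x",
      d[2L], "traits (", paste(object@traits, collapse = ", "), ")\n")
})

#' Animal identifiers
#'
#' @param x a [Pedigree-class], [GibbsChain-class] or [DerivedChain-class].
#' @return character vector of animal ids.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname animalIds
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)

#' @rdname animalIds
#' @export
setMethod("animalIds", "GibbsChain", function(x) x@info$animalIds)

#' @rdname animalIds
#' @export
setMethod("animalIds", "DerivedChain", function(x) x@animalIds)

#' Birth years per animal
#' @param x a [Pedigree-class] or [DerivedChain-class].
#' @return integer vector of birth years.
#' @export
setGeneric("birthYears", function(x) standardGeneric("birthYears"))

#' @rdname birthYears
#' @export
setMethod("birthYears", "Pedigree", function(x) x@birthYear)

#' @rdname birthYears
#' @export
setMethod("birthYears", "DerivedChain", function(x) x@birthYear)

#' Number of saved posterior samples
#' @param x a [GibbsChain-class] or [DerivedChain-class].
#' @return integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "GibbsChain", function(x) dim(x@G0)[1L])

#' @rdname nSamples
#' @export
setMethod("nSamples", "DerivedChain", function(x) dim(x@values)[3L])

#' One posterior draw of the covariance matrices
#'
#' @param chain a [GibbsChain-class].
#' @param i sample index.
#' @return list with 3x3 matrices \code{G0}, \code{K0}, \code{R0} (trait
#'   order ADFI, ADG, LMP).
#' @export
covarianceSample <- function(chain, i) {
  stopifnot(is(chain, "GibbsChain"))
  tr <- chain@info$traits
  grab <- function(a) {
    m <- matrix(a[i, , ], 3L, 3L, dimnames = list(tr, tr))
    (m + t(m)) / 2
  }
  list(G0 = grab(chain@G0), K0 = grab(chain@K0), R0 = grab(chain@R0))
}

#' Additive-value draws for one trait
#'
#' @param chain a [GibbsChain-class].
#' @param trait one of the recorded traits (default ADFI).
#' @param animals optional character ids or integer positions to subset.
#' @return matrix animals x samples.
#' @export
breedingValueSamples <- function(chain, trait = "ADFI", animals = NULL) {
  stopifnot(is(chain, "GibbsChain"))
  t <- match(match.arg(trait, chain@info$traits), chain@info$traits)
  out <- chain@additive[, t, , drop = TRUE]
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(chain@additive)[1L])
  rownames(out) <- chain@info$animalIds
  if (!is.null(animals)) out <- out[animals, , drop = FALSE]
  out
}
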