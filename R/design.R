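#' Build the trivariate model design
#'
#' Prepares the incidence structure of the animal model for ADFI, ADG and
#' LMP: corner-constrained fixed factors (year-quarter, gender, parity),
#' the trait-specific body-weight covariates (start BW for ADFI and ADG,
#' end BW for LMP; centered at their sample means), pen and animal
#' incidence, and the sparse A-inverse of the pedigree.  Animals present in
#' the pedigree but without records receive additive values through
#' relationships only.
#'
#' @param data data.frame with one row per phenotyped animal and columns
#'   \code{animal, pen, year_quarter, gender, parity, start_bw, end_bw,
#'   adfi, adg, lmp}.
#' @param ped a [Pedigree-class] containing every phenotyped animal.
#' @param factors character vector of fixed-factor column names.  The first
#'   factor keeps all its levels (it carries the intercept); later factors
#'   drop their first level (corner constraint).  Single-level factors are
#'   dropped with a warning.
#' @param covariates named list mapping each trait to its covariate column.
#' @return an object of class \code{feDesign} (a list), consumed by
#'   [runGibbs()] and [mmeSolution()].
#' @export
buildDesign <- function(data, ped,
                        factors = c("year_quarter", "gender", "parity"),
                        covariates = list(ADFI = "start_bw", ADG = "start_bw",
                                          LMP = "end_bw")) {
  stopifnot(is(ped, "Pedigree"))
  data <- as.data.frame(data)
  traits <- c("ADFI", "ADG", "LMP")
  ycols <- c("adfi", "adg", "lmp")
  need <- c("animal", "pen", factors, unique(unlist(covariates)), ycols)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ids <- as.character(data$animal)
  if (anyDuplicated(ids)) {
    stop("more than one record per animal: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  aniIdx <- match(ids, ped@id)
  if (anyNA(aniIdx)) {
    stop("phenotyped animal(s) missing from pedigree: ",
         paste(ids[is.na(aniIdx)], collapse = ", "))
  }
  y <- as.matrix(data[, ycols])
  colnames(y) <- traits
  if (!all(is.finite(y))) stop("non-finite trait values in phenotype table")
  degen <- traits[apply(y, 2L, stats::var) <= 0]
  if (length(degen)) {
    stop("degenerate trait(s) with zero variance: ",
         paste(degen, collapse = ", "))
  }

  ## corner-constrained fixed blocks; first retained factor keeps all levels
  blocks <- data.frame(factor = character(0), level = character(0),
                       count = integer(0), stringsAsFactors = FALSE)
  Fmat <- matrix(0L, nrow(data), 0L)
  keptFactors <- character(0)
  first <- TRUE
  for (f in factors) {
    fac <- factor(as.character(data[[f]]))
    if (nlevels(fac) < 2L) {
      if (!first) {
        warning("factor '", f, "' has a single level and was dropped")
        next
      }
      ## a single-level first factor still carries the intercept
    }
    lev <- levels(fac)
    use <- if (first) lev else lev[-1L]
    idx <- match(as.character(fac), use)   # NA for reference level
    idx[is.na(idx)] <- 0L
    col <- ifelse(idx == 0L, 0L, idx + nrow(blocks))
    Fmat <- cbind(Fmat, as.integer(col))
    blocks <- rbind(blocks, data.frame(
      factor = f, level = use,
      count = as.integer(table(factor(fac, levels = use))[use]),
      stringsAsFactors = FALSE))
    keptFactors <- c(keptFactors, f)
    first <- FALSE
  }
  colnames(Fmat) <- keptFactors
  nFac <- length(keptFactors)
  factorTotals <- setNames(rep(nrow(data), nFac), keptFactors)

  covX <- sapply(traits, function(t) as.numeric(data[[covariates[[t]]]]))
  covCenter <- colMeans(covX)
  covXc <- sweep(covX, 2L, covCenter)
  colnames(covXc) <- traits

  penFac <- factor(as.character(data$pen))
  penIdx <- as.integer(penFac)

  ainv <- aInverse(ped)

  structure(list(
    y = y, traits = traits,
    Fmat = Fmat, blocks = blocks, nBlocks = nrow(blocks),
    factors = keptFactors, factorTotals = factorTotals,
    covX = covXc, covCenter = covCenter, covMeans = covCenter,
    covariates = covariates,
    penIdx = penIdx, penIds = levels(penFac), nPen = nlevels(penFac),
    aniIdx = aniIdx, animalIds = ped@id, birthYear = ped@birthYear,
    phenotypedIds = ids,
    ainv = ainv, pedigree = ped
  ), class = "feDesign")
}

#' @export
print.feDesign <- function(x, ...) {
  cat("feDesign:", nrow(x$y), "records,", length(x$animalIds),
      "pedigree animals,", x$nPen, "pens\n")
  cat("  fixed blocks:", x$nBlocks, "(",
      paste(unique(x$blocks$factor), collapse = ", "), ")\n")
  invisible(x)
}

## condensed design description carried inside a GibbsChain; enough for all
## post-Gibbs computation without the raw incidence structure
.designInfo <- function(design) {
  list(traits = design$traits,
       blocks = design$blocks,
       factors = design$factors,
       factorTotals = design$factorTotals,
       covCenter = design$covCenter,
       covMeans = design$covMeans,
       animalIds = design$animalIds,
       birthYear = design$birthYear,
       phenotypedIdx = design$aniIdx,
       phenotypedIds = design$phenotypedIds,
       penIds = design$penIds)
}
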