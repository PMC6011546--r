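#' Yearly-batch basis for genetic trends
#'
#' Incidence of animals in yearly batches (by birth year).  Each animal
#' belongs to exactly one batch.
#'
#' @param birthYear integer birth year per animal.
#' @return object of class \code{feTrendBasis}: list with sorted unique
#'   \code{years}, per-animal \code{batch} index and batch \code{counts}.
#' @export
trendBasis <- function(birthYear) {
  if (anyNA(birthYear)) stop("birth year missing for some animals")
  years <- sort(unique(birthYear))
  batch <- match(birthYear, years)
  structure(list(years = years, batch = batch,
                 counts = tabulate(batch, length(years))),
            class = "feTrendBasis")
}

#' Genetic trend: yearly means of breeding values
#'
#' \code{r = (T'T)^{-1} T' a}: the per-batch mean breeding value, one entry
#' per yearly batch.
#'
#' @param a numeric vector of breeding values covering all animals of the
#'   basis.
#' @param basis an \code{feTrendBasis} from [trendBasis()].
#' @return named numeric vector, one mean per year.
#' @export
geneticTrend <- function(a, basis) {
  stopifnot(inherits(basis, "feTrendBasis"))
  if (length(a) != length(basis$batch)) {
    stop("breeding values and trend basis cover different animals")
  }
  if (any(basis$counts == 0L)) stop("empty yearly batch")
  r <- as.numeric(rowsum(a, basis$batch) / basis$counts)
  names(r) <- basis$years
  r
}

#' Remove the genetic trend from breeding values
#'
#' \code{a* = a - T r}: subtracts each animal's batch mean, so the
#' per-batch means of the result are zero.
#'
#' @inheritParams geneticTrend
#' @return numeric vector of trend-corrected breeding values.
#' @export
detrend <- function(a, basis) {
  as.numeric(a) - unname(geneticTrend(a, basis))[basis$batch]
}

#' Genetic (co)variance available for selection
#'
#' Per posterior sample, the covariance across candidates of the
#' trend-corrected breeding values of all six traits (RFI_G, RFI_P, FCR,
#' ADFI, ADG, LMP).  This is defined even for FCR, whose genetic variance
#' has no closed form: the sampler output supplies per-animal FCR breeding
#' values in every sample.
#'
#' @param derived a [DerivedChain-class].
#' @param basis optional \code{feTrendBasis}; default from the candidates'
#'   birth years.
#' @return array m x 6 x 6 of per-sample available (co)variance matrices.
#' @export
availableGeneticCovariance <- function(derived, basis = NULL) {
  stopifnot(is(derived, "DerivedChain"))
  if (dim(derived@values)[1L] < 3L) {
    stop("need at least 3 candidates to estimate available (co)variance")
  }
  if (is.null(basis)) basis <- trendBasis(derived@birthYear)
  m <- nSamples(derived)
  out <- array(NA_real_, c(m, 6L, 6L),
               dimnames = list(NULL, derived@traits, derived@traits))
  for (i in seq_len(m)) {
    astar <- apply(derived@values[, , i], 2L, detrend, basis = basis)
    out[i, , ] <- stats::cov(astar)
  }
  out
}

.directionDefaults <- c(RFI_G = "min", RFI_P = "min", FCR = "min",
                        ADFI = "min", ADG = "max", LMP = "max")

#' Superiority of a truncation-selected group
#'
#' For one posterior sample: rank candidates on the criterion trait
#' (direction applied), select the top \code{ceiling(fraction * n)}, and
#' report, for every response trait, the mean trend-corrected breeding
#' value of the selected group minus the mean over all candidates.
#' Boundary ties are broken by ascending animal id for reproducibility.
#'
#' @param astar numeric matrix candidates x traits of trend-corrected
#'   breeding values (columns named).
#' @param criterion criterion trait (a column of \code{astar}).
#' @param fraction top fraction selected, in (0, 1].
#' @param direction "min" or "max"; default per trait: minimize RFI_G,
#'   RFI_P, FCR and ADFI, maximize ADG and LMP.
#' @param ids optional candidate ids used for tie-breaking (default row
#'   names, else row order).
#' @return named numeric vector of superiorities over the response traits.
#' @export
selectedSuperiority <- function(astar, criterion, fraction = 0.10,
                                direction = NULL, ids = NULL) {
  astar <- as.matrix(astar)
  n <- nrow(astar)
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(direction)) {
    direction <- .directionDefaults[[criterion]] %||% "max"
  }
  crit <- astar[, criterion]
  if (is.null(ids)) ids <- rownames(astar) %||% as.character(seq_len(n))
  ns <- ceiling(fraction * n)
  ord <- order(if (direction == "min") crit else -crit, ids)
  sel <- ord[seq_len(ns)]
  colMeans(astar[sel, , drop = FALSE]) - colMeans(astar)
}

#' Posterior direct and correlated responses to truncation selection
#'
#' For every posterior sample: detrend the six-trait breeding values by
#' yearly batches, apply each selection scenario (one criterion trait per
#' row, favorable direction), and record the selected-group superiority for
#' every response trait.  Returns posterior means and SDs -- the analog of a
#' direct/correlated response table, with direct responses on the diagonal.
#'
#' @param derived a [DerivedChain-class].
#' @param fraction top fraction selected (default 0.10).
#' @param criteria criterion traits (default all six).
#' @param directions named character vector overriding the per-trait
#'   favorable directions.
#' @param detrendValues detrend by yearly batches first (default TRUE).
#' @return object of class \code{feResponseMatrix}: list with matrices
#'   \code{mean} and \code{sd} (criteria x response traits), the long-form
#'   \code{table} (a data.frame), and the per-sample array \code{samples}.
#' @export
responseMatrix <- function(derived, fraction = 0.10,
                           criteria = NULL, directions = NULL,
                           detrendValues = TRUE) {
  stopifnot(is(derived, "DerivedChain"))
  traits <- derived@traits
  if (is.null(criteria)) criteria <- traits
  dirs <- .directionDefaults
  if (!is.null(directions)) dirs[names(directions)] <- directions
  m <- nSamples(derived)
  basis <- trendBasis(derived@birthYear)
  sup <- array(NA_real_, c(m, length(criteria), length(traits)),
               dimnames = list(NULL, criteria, traits))
  ids <- derived@animalIds
  for (i in seq_len(m)) {
    v <- derived@values[, , i]
    astar <- if (detrendValues) apply(v, 2L, detrend, basis = basis) else v
    rownames(astar) <- ids
    for (cr in criteria) {
      sup[i, cr, ] <- selectedSuperiority(astar, cr, fraction,
                                          direction = dirs[[cr]], ids = ids)
    }
  }
  mn <- apply(sup, c(2L, 3L), mean)
  sdev <- apply(sup, c(2L, 3L), sd)
  tab <- data.frame(
    criterion = rep(criteria, times = length(traits)),
    response_trait = rep(traits, each = length(criteria)),
    posterior_mean = as.vector(mn),
    posterior_sd = as.vector(sdev),
    fraction = fraction)
  structure(list(mean = mn, sd = sdev, table = tab, samples = sup,
                 fraction = fraction, directions = dirs[criteria]),
            class = "feResponseMatrix")
}

#' @export
print.feResponseMatrix <- function(x, digits = 3L, ...) {
  cat("Posterior mean superiorities of the selected group (top ",
      100 * x$fraction, "%), criteria in rows:\n", sep = "")
  print(round(x$mean, digits))
  invisible(x)
}
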