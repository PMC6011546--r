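#' Posterior summary of an arbitrary chain functional
#'
#' Applies an extractor to every saved sample ("functions first, averaging
#' last") and summarizes the resulting scalar sequence(s): posterior mean,
#' SD, central 95 percent interval, effective sample size and Geweke z.
#'
#' @param chain a [GibbsChain-class].
#' @param extractor function of one argument, a per-sample list with
#'   elements \code{G0, K0, R0} (3x3 matrices), \code{fixed} (nBlocks x 3),
#'   \code{betaCov} (length 3) and \code{additive} (q x 3); must return a
#'   numeric scalar or a named numeric vector.
#' @return data.frame with one row per returned quantity and columns
#'   \code{mean, sd, q2.5, q97.5, ess, geweke_z}.
#' @examples
#' \donttest{
#' summarizeChain(chain, function(s) heritability(s, "ADFI"))
#' }
#' @export
summarizeChain <- function(chain, extractor) {
  stopifnot(is(chain, "GibbsChain"))
  m <- nSamples(chain)
  if (m < 2L) stop("need at least 2 samples to summarize")
  first <- extractor(.chainSample(chain, 1L))
  k <- length(first)
  vals <- matrix(NA_real_, m, k)
  vals[1L, ] <- as.numeric(first)
  for (i in 2:m) vals[i, ] <- as.numeric(extractor(.chainSample(chain, i)))
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(rowSums(vals)))[1L]
    stop("non-finite extractor value at sample ", bad)
  }
  out <- data.frame(
    mean = colMeans(vals),
    sd = apply(vals, 2L, sd),
    q2.5 = apply(vals, 2L, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(vals, 2L, quantile, probs = 0.975, names = FALSE),
    ess = apply(vals, 2L, effectiveSize),
    geweke_z = apply(vals, 2L, gewekeZ))
  rownames(out) <- names(first) %||% paste0("q", seq_len(k))
  out
}

## materialize sample i as plain matrices
.chainSample <- function(chain, i) {
  cs <- covarianceSample(chain, i)
  q <- dim(chain@additive)[1L]
  list(G0 = cs$G0, K0 = cs$K0, R0 = cs$R0,
       fixed = matrix(chain@fixed[i, , ], ncol = 3L),
       betaCov = chain@betaCov[i, ],
       additive = matrix(chain@additive[, , i], nrow = q,
                         dimnames = list(chain@info$animalIds,
                                         chain@info$traits)))
}

#' Effective sample size of a scalar chain
#'
#' Autocorrelation-time estimate using Geyer's initial positive monotone
#' sequence on the sample autocorrelations:
#' \code{ESS = m / (1 + 2 sum rho_k)}.
#'
#' @param x numeric vector of sequential samples.
#' @return effective sample size (capped at \code{length(x)}); \code{NA}
#'   for constant chains.
#' @export
effectiveSize <- function(x) {
  m <- length(x)
  if (m < 3L || sd(x) == 0 || !all(is.finite(x))) return(NA_real_)
  lagMax <- min(m - 1L, max(50L, floor(10 * log10(m) * 5)))
  rho <- as.numeric(acf(x, lag.max = lagMax, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  ## pair sums Gamma_j = rho_{2j} + rho_{2j+1}; keep while positive and
  ## non-increasing
  nPair <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (j in seq_len(nPair)) {
    g <- rho[2L * j - 1L] + rho[2L * j]
    if (g <= 0) break
    g <- min(g, prev)
    tau <- tau + 2 * g
    prev <- g
  }
  min(m, m / tau)
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the mean of the first \code{frac1} of the chain with
#' the mean of the last \code{frac2}, with standard errors corrected for
#' autocorrelation through [effectiveSize()].
#'
#' @param x numeric vector of sequential samples.
#' @param frac1,frac2 fractions defining the early and late windows
#'   (defaults 0.1 and 0.5).
#' @return z statistic; \code{NA} for constant or too-short chains.
#' @export
gewekeZ <- function(x, frac1 = 0.1, frac2 = 0.5) {
  m <- length(x)
  if (m < 20L || sd(x) == 0) return(NA_real_)
  x1 <- x[seq_len(max(2L, floor(frac1 * m)))]
  x2 <- x[(m - max(2L, floor(frac2 * m)) + 1L):m]
  se2 <- function(v) {
    e <- effectiveSize(v)
    if (!is.finite(e) || e <= 0) return(NA_real_)
    var(v) / e
  }
  s <- se2(x1) + se2(x2)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  (mean(x1) - mean(x2)) / sqrt(s)
}

#' Convergence diagnostics for the standard chain quantities
#'
#' ESS and Geweke z for the variance components, heritabilities and
#' genetic correlations of the three recorded traits.
#'
#' @param chain a [GibbsChain-class].
#' @return data.frame with one row per quantity.
#' @export
chainDiagnostics <- function(chain) {
  stopifnot(is(chain, "GibbsChain"))
  if (nSamples(chain) < 50L) stop("need at least 50 samples for diagnostics")
  tr <- chain@info$traits
  summarizeChain(chain, function(s) {
    g <- diag(s$G0)
    out <- c(setNames(g, paste0("varG_", tr)),
             setNames(diag(s$R0), paste0("varR_", tr)),
             setNames(diag(s$K0), paste0("varPen_", tr)),
             setNames(vapply(1:3, function(t) heritability(s, t), 0),
                      paste0("h2_", tr)),
             corG_ADFI_ADG = s$G0[1L, 2L] / sqrt(g[1L] * g[2L]),
             corG_ADFI_LMP = s$G0[1L, 3L] / sqrt(g[1L] * g[3L]),
             corG_ADG_LMP = s$G0[2L, 3L] / sqrt(g[2L] * g[3L]))
    out
  })[, c("ess", "geweke_z")]
}

## full-precision CSV helpers: doubles survive a write/read round trip
.fwriteFull <- function(dt, path) {
  dt <- data.table::as.data.table(dt)
  for (j in names(dt)) {
    if (is.double(dt[[j]])) data.table::set(dt, j = j,
                                            value = sprintf("%.17g", dt[[j]]))
  }
  data.table::fwrite(dt, path)
}

#' Persist a chain to a directory of delimited text files
#'
#' Writes the covariance samples (one row per sample, flattened 3x3
#' matrices), the location-effect samples, the per-animal additive-value
#' samples (long format) and a JSON metadata file.  Values are written at
#' full precision, so [readChain()] reproduces the chain bit for bit.
#'
#' @param chain a [GibbsChain-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeChain <- function(chain, dir) {
  stopifnot(is(chain, "GibbsChain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- nSamples(chain)
  tr <- chain@info$traits
  pair <- as.vector(outer(tr, tr, paste, sep = "_"))
  flat <- function(a) {
    x <- matrix(a, m, 9L)
    colnames(x) <- pair
    x
  }
  cov <- data.frame(sample = seq_len(m),
                    setNames(as.data.frame(flat(chain@G0)),
                             paste0("G0_", pair)),
                    setNames(as.data.frame(flat(chain@K0)),
                             paste0("K0_", pair)),
                    setNames(as.data.frame(flat(chain@R0)),
                             paste0("R0_", pair)))
  .fwriteFull(cov, file.path(dir, "covariances.csv"))

  nB <- dim(chain@fixed)[2L]
  fx <- data.frame(sample = rep(seq_len(m), nB),
                   block = rep(seq_len(nB), each = m),
                   factor = rep(chain@info$blocks$factor, each = m),
                   level = rep(chain@info$blocks$level, each = m),
                   ADFI = as.vector(chain@fixed[, , 1L]),
                   ADG = as.vector(chain@fixed[, , 2L]),
                   LMP = as.vector(chain@fixed[, , 3L]))
  .fwriteFull(fx, file.path(dir, "fixed.csv"))
  .fwriteFull(data.frame(sample = seq_len(m),
                         ADFI = chain@betaCov[, 1L],
                         ADG = chain@betaCov[, 2L],
                         LMP = chain@betaCov[, 3L]),
              file.path(dir, "covariate.csv"))

  q <- dim(chain@additive)[1L]
  add <- data.frame(sample = rep(seq_len(m), each = q),
                    animal = rep(chain@info$animalIds, m),
                    ADFI = as.vector(chain@additive[, 1L, ]),
                    ADG = as.vector(chain@additive[, 2L, ]),
                    LMP = as.vector(chain@additive[, 3L, ]))
  .fwriteFull(add, file.path(dir, "additive.csv"))

  n <- dim(chain@residuals)[1L]
  if (n > 0L) {
    res <- data.frame(sample = rep(seq_len(m), each = n),
                      animal = rep(chain@info$phenotypedIds, m),
                      ADFI = as.vector(chain@residuals[, 1L, ]),
                      ADG = as.vector(chain@residuals[, 2L, ]),
                      LMP = as.vector(chain@residuals[, 3L, ]))
    .fwriteFull(res, file.path(dir, "residuals.csv"))
  }
  info <- chain@info
  ## named atomic vectors lose names in JSON arrays; store them as objects
  for (nm in c("factorTotals", "covCenter", "covMeans")) {
    info[[nm]] <- as.list(setNames(unname(info[[nm]]),
                                   names(info[[nm]]) %||%
                                     (if (nm == "factorTotals") info$factors
                                      else info$traits)))
  }
  meta <- c(chain@meta,
            list(info = info, nSamples = m,
                 hasResiduals = n > 0L))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a chain written by [writeChain()]
#'
#' @param dir directory containing the chain files.
#' @return a [GibbsChain-class].
#' @export
readChain <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("no chain found at ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  info <- meta$info
  info$blocks <- as.data.frame(info$blocks)
  info$factorTotals <- unlist(info$factorTotals)
  info$covCenter <- unlist(info$covCenter)
  info$covMeans <- unlist(info$covMeans)
  m <- meta$nSamples
  cov <- data.table::fread(file.path(dir, "covariances.csv"))
  unflat <- function(prefix) {
    a <- as.matrix(cov[, paste0(prefix, "_",
                                as.vector(outer(info$traits, info$traits,
                                                paste, sep = "_"))),
                       with = FALSE])
    array(a, c(m, 3L, 3L))
  }
  fx <- data.table::fread(file.path(dir, "fixed.csv"))
  nB <- max(fx$block)
  fixed <- array(NA_real_, c(m, nB, 3L))
  for (t in 1:3) {
    fixed[, , t] <- matrix(fx[[c("ADFI", "ADG", "LMP")[t]]], m, nB)
  }
  cvb <- data.table::fread(file.path(dir, "covariate.csv"))
  add <- data.table::fread(file.path(dir, "additive.csv"))
  q <- length(info$animalIds)
  additive <- array(NA_real_, c(q, 3L, m))
  for (t in 1:3) {
    additive[, t, ] <- matrix(add[[c("ADFI", "ADG", "LMP")[t]]], q, m)
  }
  residuals <- array(0, c(0L, 0L, 0L))
  if (isTRUE(meta$hasResiduals)) {
    res <- data.table::fread(file.path(dir, "residuals.csv"))
    n <- length(info$phenotypedIds)
    residuals <- array(NA_real_, c(n, 3L, m))
    for (t in 1:3) {
      residuals[, t, ] <- matrix(res[[c("ADFI", "ADG", "LMP")[t]]], n, m)
    }
  }
  new("GibbsChain",
      G0 = unflat("G0"), K0 = unflat("K0"), R0 = unflat("R0"),
      fixed = fixed, betaCov = as.matrix(cvb[, c("ADFI", "ADG", "LMP")]),
      additive = additive, residuals = residuals,
      info = info,
      meta = meta[c("nIter", "burnIn", "thin", "seed", "fixedCovariances",
                    "priorNu")])
}
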