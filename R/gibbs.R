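#' Fit the trivariate animal model by Gibbs sampling
#'
#' Samples the joint posterior of all location effects and the covariance
#' matrices G0 (additive genetic), K0 (pen) and R0 (residual) of the
#' trivariate model for ADFI, ADG and LMP.  Priors are flat for all "fixed"
#' location parameters and inverse Wishart for the covariance matrices; the
#' default \code{priorNu = -4} with a zero scale is the improper flat limit
#' for 3x3 matrices.  Location effects with shared incidence across traits
#' (factor levels, pens, animals) are drawn as 3-trait blocks, which keeps
#' mixing healthy under the strong genetic correlation between ADFI and ADG.
#'
#' The default chain length (60000 iterations, 10000 burn-in, thinning 25)
#' is a desk-scale choice; longer chains are a matter of configuration.
#'
#' @param data phenotype data.frame (see [buildDesign()]) or an
#'   \code{feDesign} already built (then \code{ped} is ignored).
#' @param ped a [Pedigree-class]; required when \code{data} is a data.frame.
#' @param nIter,burnIn,thin chain length, burn-in, thinning interval.
#' @param seed integer seed; same seed and configuration give bit-identical
#'   chains.
#' @param fixCovariances optional list with SPD matrices \code{G0, K0, R0};
#'   when given, covariance updates are skipped (validation mode: posterior
#'   means of location effects then equal the mixed-model-equations solution
#'   up to Monte-Carlo error, see [mmeSolution()]).
#' @param priorNu inverse-Wishart degrees of freedom; the flat limit is
#'   \code{-(dim + 1) = -4}.
#' @param priorScale optional list \code{G0, K0, R0} of 3x3 prior scale
#'   matrices (default zero).
#' @param startCov optional list \code{G0, K0, R0} of starting values;
#'   default carves the phenotypic sample covariance into 40/10/50 percent.
#' @param storeResiduals keep per-record residual samples (needed by
#'   [fcrPhenotypicDeviation()]).
#' @return a [GibbsChain-class].
#' @examples
#' \donttest{
#' sim <- simulatePopulation(simConfig(nFounders = 80, nGenerations = 2,
#'   matingsPerGeneration = 15, offspringPerMating = 6), seed = 1)
#' chain <- runGibbs(sim$phenotypes, sim$pedigree,
#'                   nIter = 2000, burnIn = 500, thin = 5, seed = 1)
#' summary(heritability(chain, "ADFI"))
#' }
#' @export
runGibbs <- function(data, ped = NULL, nIter = 60000L, burnIn = 10000L,
                     thin = 25L, seed = 1L, fixCovariances = NULL,
                     priorNu = -4, priorScale = NULL, startCov = NULL,
                     storeResiduals = TRUE) {
  design <- if (inherits(data, "feDesign")) data else buildDesign(data, ped)
  nIter <- as.integer(nIter); burnIn <- as.integer(burnIn)
  thin <- as.integer(thin)
  if (nIter <= burnIn) stop("nIter must exceed burnIn")
  if (thin < 1L) stop("thin must be >= 1")
  n <- nrow(design$y)
  q <- length(design$animalIds)
  zero3 <- matrix(0, 3L, 3L)
  scale <- list(G0 = zero3, K0 = zero3, R0 = zero3)
  if (!is.null(priorScale)) scale[names(priorScale)] <- priorScale
  updateCov <- is.null(fixCovariances)
  if (updateCov) {
    ## improper flat-limit prior needs enough levels per random term
    lv <- c(animal = q, pen = design$nPen, residual = n)
    low <- lv[lv + priorNu <= 2]
    if (length(low)) {
      stop("too few levels for the flat inverse-Wishart limit (need df > 2): ",
           paste(names(low), "=", low, collapse = ", "),
           "; supply a proper priorNu/priorScale")
    }
  }
  .checkSPD <- function(M, what) {
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)) ||
        inherits(try(chol(M), silent = TRUE), "try-error"))
      stop(what, " must be symmetric positive definite")
    M
  }
  if (!updateCov) {
    fixCovariances <- lapply(fixCovariances, function(m) unname(as.matrix(m)))
    for (nm in c("G0", "K0", "R0")) .checkSPD(fixCovariances[[nm]], nm)
    start <- fixCovariances
  } else if (!is.null(startCov)) {
    start <- lapply(startCov, function(m) unname(as.matrix(m)))
  } else {
    Sy <- stats::cov(design$y)
    start <- list(G0 = 0.4 * Sy + diag(1e-6, 3L),
                  K0 = 0.1 * Sy + diag(1e-6, 3L),
                  R0 = 0.5 * Sy + diag(1e-6, 3L))
  }
  csc <- .ainvCSC(design$ainv)
  set.seed(seed)
  res <- .gibbs_core(design$y, design$Fmat, design$nBlocks, design$covX,
                     design$penIdx, design$nPen, design$aniIdx, q,
                     csc$p, csc$i, csc$x,
                     start$G0, start$K0, start$R0,
                     priorNu, scale$G0, scale$K0, scale$R0,
                     nIter, burnIn, thin, updateCov, storeResiduals)
  m <- res$nSave
  shape <- function(v, d) {
    dim(v) <- d
    v
  }
  new("GibbsChain",
      G0 = shape(res$g0, c(m, 3L, 3L)),
      K0 = shape(res$k0, c(m, 3L, 3L)),
      R0 = shape(res$r0, c(m, 3L, 3L)),
      fixed = shape(res$fixed, c(m, design$nBlocks, 3L)),
      betaCov = shape(res$betaCov, c(m, 3L)),
      additive = shape(res$additive, c(q, 3L, m)),
      residuals = if (storeResiduals) shape(res$residuals, c(n, 3L, m))
                  else array(0, c(0L, 0L, 0L)),
      info = .designInfo(design),
      meta = list(nIter = nIter, burnIn = burnIn, thin = thin, seed = seed,
                  fixedCovariances = !updateCov, priorNu = priorNu))
}

#' Heritability from one covariance draw or a whole chain
#'
#' \code{h2 = G0[t,t] / (G0[t,t] + K0[t,t] + R0[t,t])}.  The denominator is
#' the phenotypic variance P0 = G0 + K0 + R0, i.e. pen variance counts as
#' phenotypic; set \code{includePen = FALSE} to exclude it.
#'
#' @param x a list with matrices \code{G0, K0, R0} (one draw), or a
#'   [GibbsChain-class] (then a vector of per-sample values is returned).
#' @param trait trait name or index (ADFI, ADG, LMP).
#' @param includePen include the pen variance in the denominator.
#' @return numeric scalar or per-sample vector in (0, 1).
#' @export
setGeneric("heritability",
           function(x, trait = "ADFI", includePen = TRUE)
             standardGeneric("heritability"))

#' @rdname heritability
#' @export
setMethod("heritability", "list", function(x, trait = "ADFI",
                                           includePen = TRUE) {
  t <- if (is.character(trait)) match(trait, colnames(x$G0) %||%
                                        c("ADFI", "ADG", "LMP")) else trait
  g <- x$G0[t, t]
  g / (g + (if (includePen) x$K0[t, t] else 0) + x$R0[t, t])
})

#' @rdname heritability
#' @export
setMethod("heritability", "GibbsChain", function(x, trait = "ADFI",
                                                 includePen = TRUE) {
  t <- if (is.character(trait)) match(trait, x@info$traits) else trait
  g <- x@G0[, t, t]
  g / (g + (if (includePen) x@K0[, t, t] else 0) + x@R0[, t, t])
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direct solution of the mixed-model equations
#'
#' Solves Henderson's mixed-model equations of the trivariate model at
#' known covariance matrices, as a deterministic cross-check of the sampler:
#' with covariances fixed at the same values and flat priors on the fixed
#' effects, the Gibbs posterior means of all location effects converge to
#' this solution.
#'
#' @param design an \code{feDesign} from [buildDesign()].
#' @param G0,K0,R0 known 3x3 covariance matrices (trait order ADFI, ADG,
#'   LMP).
#' @return list with components \code{fixed} (nBlocks x 3), \code{betaCov}
#'   (length-3 covariate regressions), \code{additive} (q x 3 BLUP matrix
#'   with animal ids as rownames) and \code{pen} (nPen x 3).
#' @export
mmeSolution <- function(design, G0, K0, R0) {
  stopifnot(inherits(design, "feDesign"))
  n <- nrow(design$y)
  q <- length(design$animalIds)
  nB <- design$nBlocks
  nP <- design$nPen
  Q <- solve(R0)
  Ginv <- solve(G0)
  Kinv <- solve(K0)

  Xf <- Matrix::sparseMatrix(
    i = rep(seq_len(n), ncol(design$Fmat))[as.vector(design$Fmat) > 0],
    j = as.vector(design$Fmat)[as.vector(design$Fmat) > 0],
    x = 1, dims = c(n, nB))
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = design$aniIdx, x = 1,
                            dims = c(n, q))
  S <- Matrix::sparseMatrix(i = seq_len(n), j = design$penIdx, x = 1,
                            dims = c(n, nP))
  W <- lapply(1:3, function(t) cbind(Xf, design$covX[, t, drop = FALSE], Z, S))
  P <- nB + 1L + q + nP

  Ctt <- function(t, u) Q[t, u] * Matrix::crossprod(W[[t]], W[[u]])
  LHS <- rbind(cbind(Ctt(1, 1), Ctt(1, 2), Ctt(1, 3)),
               cbind(Ctt(2, 1), Ctt(2, 2), Ctt(2, 3)),
               cbind(Ctt(3, 1), Ctt(3, 2), Ctt(3, 3)))
  ## random-effect priors on the block diagonal of each trait pair
  aPos <- nB + 1L + seq_len(q)
  pPos <- nB + 1L + q + seq_len(nP)
  ii <- jj <- integer(0); xx <- numeric(0)
  ainvT <- as(as(design$ainv, "generalMatrix"), "TsparseMatrix")
  for (t in 1:3) for (u in 1:3) {
    off_t <- (t - 1L) * P
    off_u <- (u - 1L) * P
    ii <- c(ii, off_t + nB + 1L + (ainvT@i + 1L), off_t + pPos)
    jj <- c(jj, off_u + nB + 1L + (ainvT@j + 1L), off_u + pPos)
    xx <- c(xx, Ginv[t, u] * ainvT@x, rep(Kinv[t, u], nP))
  }
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * P, 3L * P))
  LHS <- LHS + D
  RHS <- unlist(lapply(1:3, function(t) {
    Reduce(`+`, lapply(1:3, function(u)
      Q[t, u] * as.numeric(Matrix::crossprod(W[[t]], design$y[, u]))))
  }))
  sol <- as.numeric(Matrix::solve(LHS, RHS))
  perTrait <- matrix(sol, ncol = 3L)
  additive <- perTrait[aPos, , drop = FALSE]
  rownames(additive) <- design$animalIds
  colnames(additive) <- design$traits
  list(fixed = perTrait[seq_len(nB), , drop = FALSE],
       betaCov = perTrait[nB + 1L, ],
       additive = additive,
       pen = perTrait[pPos, , drop = FALSE])
}
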