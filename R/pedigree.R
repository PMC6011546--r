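#' Construct a pedigree
#'
#' Builds a topologically sorted [Pedigree-class] from parallel vectors.
#' Unknown parents are coded \code{0}, \code{""} or \code{NA}.  Parents that
#' are referenced but never listed as animals are added as founders with
#' unknown birth year.  Records may arrive in any order; they are re-sorted
#' so that parents precede offspring.  Cyclic parentage (an animal being its
#' own ancestor) is an error naming the cycle.
#'
#' @param animal character or integer animal ids (unique).
#' @param sire,dam parent ids, same length as \code{animal}.
#' @param birthYear integer birth years.
#' @return a [Pedigree-class].
#' @examples
#' p <- pedigree(c("S", "D", "O"), c(0, 0, "S"), c(0, 0, "D"),
#'               c(2007L, 2007L, 2008L))
#' relationshipMatrix(p)
#' @export
pedigree <- function(animal, sire, dam, birthYear) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  unk <- function(x) is.na(x) | x == "0" | x == "" | x == "NA"
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  self <- which(!is.na(sire) & sire == animal | !is.na(dam) & dam == animal)
  if (length(self)) {
    stop("animal(s) listed as their own parent: ",
         paste(animal[self], collapse = ", "))
  }
  extra <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
    birthYear <- c(rep(NA_integer_, length(extra)), as.integer(birthYear))
  } else {
    birthYear <- as.integer(birthYear)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  ## Kahn topological sort, stable in input order
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order) < n) {
    left <- setdiff(seq_len(n), order)
    ## walk parent links among the leftovers to exhibit a cycle
    v <- left[1L]
    path <- v
    repeat {
      p <- c(si[v], di[v])
      v <- p[!is.na(p) & p %in% left][1L]
      if (v %in% path) {
        cyc <- c(path[which(path == v)[1L]:length(path)], v)
        stop("cyclic parentage: ", paste(animal[cyc], collapse = " -> "))
      }
      path <- c(path, v)
    }
  }
  pos <- integer(n)
  pos[order] <- seq_len(n)
  new("Pedigree",
      id = animal[order],
      sire = ifelse(is.na(si[order]), 0L, pos[si[order]]),
      dam = ifelse(is.na(di[order]), 0L, pos[di[order]]),
      birthYear = birthYear[order])
}

#' Read a pedigree file
#'
#' Reads a delimited file with header columns \code{animal,sire,dam,birth_year}
#' (case-insensitive; extra columns ignored).  Unknown parents are coded
#' \code{0} or empty.  The pedigree is topologically sorted on load.
#'
#' @param path path to a delimited text file.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  dt <- data.table::fread(path, colClasses = "character")
  names(dt) <- tolower(names(dt))
  need <- c("animal", "sire", "dam", "birth_year")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("pedigree file lacks column(s): ", paste(miss, collapse = ", "))
  }
  pedigree(dt$animal, dt$sire, dt$dam, suppressWarnings(as.integer(dt$birth_year)))
}

#' Write a pedigree to CSV
#'
#' Inverse of [readPedigree()]: columns \code{animal,sire,dam,birth_year},
#' unknown parents written as \code{0}.
#'
#' @param ped a [Pedigree-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePedigree <- function(ped, path) {
  stopifnot(is(ped, "Pedigree"))
  idOf <- function(ix) ifelse(ix == 0L, "0", ped@id[pmax(ix, 1L)])
  dt <- data.table::data.table(animal = ped@id, sire = idOf(ped@sire),
                               dam = idOf(ped@dam), birth_year = ped@birthYear)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Additive genetic relationship matrix (tabular method)
#'
#' Builds the dense numerator relationship matrix A by the tabular method:
#' \code{A[i,i] = 1 + 0.5 A[s,d]} and \code{A[i,j] = 0.5 (A[s,j] + A[d,j])}
#' for j preceding i, unknown parents contributing zero.  Dense storage is
#' only sensible for modest pedigrees; the sampler itself only ever uses the
#' sparse inverse from [aInverse()].
#'
#' @param ped a [Pedigree-class].
#' @param maxAnimals refuse to allocate beyond this many animals
#'   (default 10000).
#' @return symmetric numeric matrix with dimnames = animal ids; the diagonal
#'   is 1 + the inbreeding coefficient.
#' @export
relationshipMatrix <- function(ped, maxAnimals = 10000L) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  if (n > maxAnimals) {
    stop("pedigree has ", n, " animals; dense A refused above ", maxAnimals,
         " (raise maxAnimals deliberately, or use aInverse())")
  }
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  s <- ped@sire
  d <- ped@dam
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s[i] > 0L) A[s[i], j] else 0) +
                    (if (d[i] > 0L) A[d[i], j] else 0))
      A[i, j] <- row
      A[j, i] <- row
    }
  }
  A
}

#' Inbreeding coefficients (Meuwissen-Luo recursion)
#'
#' Computes F per animal without forming A, by evaluating the diagonal
#' element of a virtual progeny of each animal's parents through the
#' ancestor-tracing recursion of the L D L' factorisation of A.
#'
#' @param ped a [Pedigree-class].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreedingCoefficients <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  s <- ped@sire
  d <- ped@dam
  F <- numeric(n)
  D <- numeric(n) # Mendelian sampling variance per animal, needs parental F
  for (i in seq_len(n)) {
    D[i] <- if (s[i] > 0L && d[i] > 0L) {
      0.5 - 0.25 * (F[s[i]] + F[d[i]])
    } else if (s[i] > 0L) {
      0.75 - 0.25 * F[s[i]]
    } else if (d[i] > 0L) {
      0.75 - 0.25 * F[d[i]]
    } else 1
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
      next
    }
    ## a(s,d) via virtual progeny v with parents s,d:
    ## a_vv = sum_j L_vj^2 D_j over v and its ancestors, and F_i = a_vv - 1.
    L <- numeric(i)
    Dv <- 0.5 - 0.25 * (F[s[i]] + F[d[i]])
    a <- Dv # L_vv = 1, contribution of v itself
    L[s[i]] <- 0.5
    L[d[i]] <- 0.5
    for (j in max(s[i], d[i]):1L) {
      if (L[j] == 0) next
      a <- a + L[j]^2 * D[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- a - 1
  }
  names(F) <- ped@id
  F
}

#' Sparse inverse of the relationship matrix
#'
#' Assembles A-inverse directly from per-animal contributions (Henderson's
#' rules), accounting for inbreeding through the Mendelian sampling
#' variances from [inbreedingCoefficients()].
#'
#' @param ped a [Pedigree-class].
#' @return a sparse symmetric matrix (\code{Matrix::dsCMatrix}) with
#'   dimnames = animal ids.
#' @export
aInverse <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  s <- ped@sire
  d <- ped@dam
  F <- inbreedingCoefficients(ped)
  Fs <- numeric(n)
  Fs[s > 0L] <- F[s[s > 0L]]
  Fd <- numeric(n)
  Fd[d > 0L] <- F[d[d > 0L]]
  m <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
       ifelse(s > 0L, 0.75 - 0.25 * Fs,
       ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
  alpha <- 1 / m
  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, v) {
    ## keep lower triangle (row >= col) for the symmetric constructor
    ii <<- c(ii, pmax(i, j))
    jj <<- c(jj, pmin(i, j))
    xx <<- c(xx, v)
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  both <- which(s > 0L & d > 0L)
  sOnly <- which(s > 0L & d == 0L)
  dOnly <- which(s == 0L & d > 0L)
  for (set in list(list(w = both, p = s), list(w = both, p = d),
                   list(w = sOnly, p = s), list(w = dOnly, p = d))) {
    w <- set$w
    if (!length(w)) next
    p <- set$p[w]
    add(w, p, -alpha[w] / 2)
    add(p, p, alpha[w] / 4)
  }
  if (length(both)) add(s[both], d[both], alpha[both] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            symmetric = TRUE,
                            dimnames = list(ped@id, ped@id))
  M
}

## full-pattern compressed-sparse-column view of a symmetric sparse matrix,
## as flat vectors for the C++ sampler
.ainvCSC <- function(ainv) {
  g <- as(as(ainv, "generalMatrix"), "CsparseMatrix")
  list(p = g@p, i = g@i, x = g@x, n = nrow(g))
}
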