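# Pedigree additive relationship matrix A (tabular method, exact inbreeding)
# and its sparse inverse by Henderson's rules, used by the polygenic sampler.

# Validate and index a pedigree: returns list(sire_idx, dam_idx) with 0 for
# unknown, checking that parents precede offspring (which also rules out
# cycles and self-ancestry in an ordered list).
ped_index <- function(pedigree) {
  stopifnot(is.data.frame(pedigree),
            all(c("id", "sire", "dam") %in% names(pedigree)))
  id <- pedigree$id
  if (anyDuplicated(id)) stop("duplicate animal ids in pedigree")
  si <- match(pedigree$sire, id, nomatch = 0L)
  di <- match(pedigree$dam, id, nomatch = 0L)
  unknown_s <- pedigree$sire %in% c(0, NA)
  unknown_d <- pedigree$dam %in% c(0, NA)
  if (any(si == 0L & !unknown_s) || any(di == 0L & !unknown_d))
    stop("pedigree refers to parents that are not listed as animals")
  si[unknown_s] <- 0L
  di[unknown_d] <- 0L
  n <- length(id)
  if (any(si >= seq_len(n) & si > 0L) || any(di >= seq_len(n) & di > 0L))
    stop("pedigree is not sorted parents-first (or contains a cycle); ",
         "topologically sort so every parent precedes its offspring")
  list(sire = si, dam = di, n = n, id = id)
}

#' Additive relationship matrix by the tabular method
#'
#' Computes the pedigree-derived additive genetic relationship matrix A
#' recursively: `a_ii = 1 + 0.5 * a(sire_i, dam_i)` and, for earlier j,
#' `a_ij = 0.5 * (a(j, sire_i) + a(j, dam_i))`, with an unknown parent
#' contributing 0. Inbreeding is therefore accounted for exactly; diagonal
#' entries equal 1 plus the animal's inbreeding coefficient.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (0 or NA =
#'   unknown), parents listed before offspring.
#' @return symmetric n x n matrix with animal ids as dimnames.
#' @export
build_A <- function(pedigree) {
  px <- ped_index(pedigree)
  n <- px$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- px$sire[i]
    d <- px$dam[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row_s <- if (s > 0L) A[s, j] else 0
      row_d <- if (d > 0L) A[d, j] else 0
      aij <- 0.5 * (row_s + row_d)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(px$id, px$id)
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A^-1 directly from the pedigree by Henderson's rules with exact
#' inbreeding: for animal i with Mendelian sampling variance
#' `d_i = 1 - 0.25 * (a_ss + a_dd)` (an unknown parent contributing 0, so a
#' founder has `d = 1` and a non-inbred, non-founder `d = 0.5`), add `1/d_i`
#' at (i,i), `-1/(2 d_i)` at (i, parent), and `1/(4 d_i)` at each
#' (parent, parent) pair. The parental diagonal entries `a_ss`, `a_dd` come
#' from the tabular A, so the construction is exact for inbred pedigrees.
#'
#' @param pedigree data.frame as in [build_A()].
#' @param A optional precomputed [build_A()] result (diagonal is reused).
#' @return a `dgCMatrix` (both triangles stored) of size n x n.
#' @export
pedigree_ainverse <- function(pedigree, A = NULL) {
  px <- ped_index(pedigree)
  n <- px$n
  if (is.null(A)) A <- build_A(pedigree)
  adiag <- diag(A)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  pos <- 0L
  add <- function(i, j, v) {
    pos <<- pos + 1L
    ii[pos] <<- i; jj[pos] <<- j; xx[pos] <<- v
  }
  for (i in seq_len(n)) {
    s <- px$sire[i]
    d <- px$dam[i]
    a_ss <- if (s > 0L) adiag[s] else 0
    a_dd <- if (d > 0L) adiag[d] else 0
    di <- 1 - 0.25 * (a_ss + a_dd)
    w <- 1 / di
    add(i, i, w)
    pars <- c(s, d)[c(s, d) > 0L]
    for (par in pars) {
      add(i, par, -w / 2); add(par, i, -w / 2)
    }
    for (p1 in pars) for (p2 in pars) add(p1, p2, w / 4)
  }
  ii <- ii[seq_len(pos)]; jj <- jj[seq_len(pos)]; xx <- xx[seq_len(pos)]
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(px$id, px$id), repr = "C")
}
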