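# Dense two-phase tableau simplex with Bland's rule. Small problems only
# (the 3x3-histogram transportation LP has 81 variables and 17 independent
# constraints); no LP package is assumed.
simplex_lp <- function(A, b, cost, tol = 1e-10) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  pivot_loop <- function(tab, basis, ncols) {
    m <- nrow(tab) - 1L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      red <- tab[m + 1L, seq_len(ncols)]
      enter <- which(red < -tol)
      if (!length(enter)) return(list(tab = tab, basis = basis))
      # Dantzig rule for speed; Bland's rule after many iterations to
      # guarantee termination under degeneracy
      j <- if (iter <= 300L) enter[which.min(red[enter])] else enter[1L]
      col <- tab[seq_len(m), j]
      pos <- which(col > tol)
      if (!length(pos)) stop("LP unbounded")
      ratio <- tab[pos, ncol(tab)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]               # Bland tie-break
      tab[i, ] <- tab[i, ] / tab[i, j]
      piv <- tab[, j]
      piv[i] <- 0
      tab <- tab - outer(piv, tab[i, ])               # one rank-1 update
      basis[i] <- j
    }
  }

  # phase 1: artificial variables form the starting basis
  tab <- rbind(cbind(A, diag(m), b),
               c(rep(0, n), rep(1, m), 0))
  basis <- n + seq_len(m)
  for (i in seq_len(m)) tab[m + 1L, ] <- tab[m + 1L, ] - tab[i, ]
  r1 <- pivot_loop(tab, basis, n + m)
  if (-r1$tab[m + 1L, ncol(tab)] > 1e-7) stop("LP infeasible")
  tab <- r1$tab; basis <- r1$basis
  # drive any degenerate artificials out of the basis
  for (i in which(basis > n)) {
    j <- which(abs(tab[i, seq_len(n)]) > tol)[1L]
    if (is.na(j)) next                                # redundant zero row
    tab[i, ] <- tab[i, ] / tab[i, j]
    for (r in seq_len(m + 1L)[-i])
      tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
    basis[i] <- j
  }
  # phase 2
  tab2 <- rbind(tab[seq_len(m), c(seq_len(n), n + m + 1L), drop = FALSE],
                c(cost, 0))
  for (i in seq_len(m)) if (basis[i] <= n)
    tab2[m + 1L, ] <- tab2[m + 1L, ] - tab2[m + 1L, basis[i]] * tab2[i, ]
  r2 <- pivot_loop(tab2, basis, n)
  x <- numeric(n)
  ok <- r2$basis <= n
  x[r2$basis[ok]] <- r2$tab[seq_len(m), n + 1L][ok]
  list(x = x, value = sum(cost * x))
}

#' Euclidean ground metric for histogram bins arranged on a grid
#'
#' Bins are laid out on an `nrow x ncol` grid in R's column-major vector
#' order; the distance between two bins is the Euclidean distance between
#' their grid coordinates, so horizontally or vertically adjacent bins are at
#' unity distance.
#'
#' @param nrow,ncol grid dimensions (default the 3 x 3 preference grid).
#' @return `(nrow*ncol) x (nrow*ncol)` distance matrix.
#' @export
emd_grid_metric <- function(nrow = 3L, ncol = 3L) {
  coords <- cbind(rep(seq_len(nrow), ncol), rep(seq_len(ncol), each = nrow))
  as.matrix(stats::dist(coords))
}

#' Earth mover's distance between two histograms
#'
#' Solves the balanced transportation problem
#' `min sum f_ij d_ij` subject to row sums `p`, column sums `q`, `f >= 0`,
#' exactly (dense simplex). Total masses must agree to within `1e-6`
#' relative.
#'
#' @param p,q non-negative histograms of equal length and equal total mass.
#' @param ground ground-distance matrix; default [emd_grid_metric()] for a
#'   3 x 3 grid when `length(p) == 9`.
#' @return the minimal transport cost (total mass moved x distance).
#' @export
emd <- function(p, q, ground = NULL) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (is.null(ground)) {
    if (length(p) != 9L) stop("supply a ground metric for non-3x3 histograms")
    ground <- emd_grid_metric()
  }
  sp <- sum(p); sq <- sum(q)
  if (sp == 0 && sq == 0) return(0)
  if (abs(sp - sq) > 1e-6 * max(sp, sq)) stop("unbalanced histograms")
  q <- q * (sp / sq)
  n <- length(p)
  # constraints: n row sums + (n-1) column sums (last is redundant)
  nv <- n * n  # f[i,j], column-major in j-major blocks: var k = (j-1)*n + i
  A <- matrix(0, 2L * n - 1L, nv)
  for (i in seq_len(n)) A[i, (seq_len(n) - 1L) * n + i] <- 1  # sum_j f[i,j] = p_i
  for (j in seq_len(n - 1L)) A[n + j, (j - 1L) * n + seq_len(n)] <- 1
  b <- c(p, q[-n])
  cost <- as.vector(ground)  # ground[i,j] at var (j-1)*n + i: column-major match
  simplex_lp(A, b, cost)$value
}
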