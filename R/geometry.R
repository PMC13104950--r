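#' Soft-normalize trial-mean PETHs into an aligned activity matrix
#'
#' Each unit's rates are divided by its maximum firing rate plus `c` (default
#' 5 Hz), so a unit peaking at 45 Hz maps to a maximum of 0.9 and a silent
#' unit stays at zero.
#'
#' @param X T x N matrix of trial-mean PETH rates (time bins x units), Hz.
#' @param c soft-normalization constant (Hz).
#' @return T x N normalized matrix.
#' @export
soft_normalize <- function(X, c = 5) {
  mx <- apply(X, 2L, max)
  sweep(X, 2L, mx + c, "/")
}

#' Principal components decomposition of an aligned activity matrix
#'
#' Columns (units) are mean-centred over time (config-switchable), then `X`
#' is decomposed by SVD into scores `P` (T x P) and loadings `Q` (P x N, rows
#' orthonormal), so `X ~ P %*% Q`. `Q` projects neural space into PC space.
#'
#' @param X T x N matrix.
#' @param center mean-centre columns before the SVD (default TRUE).
#' @return list of class `pca_decomposition`: `scores`, `loadings`,
#'   `singular_values`, `explained` (variance fractions summing to 1 over
#'   full rank), `center` (column means used).
#' @export
pca_decompose <- function(X, center = TRUE) {
  stopifnot(nrow(X) >= 2L, ncol(X) >= 2L)
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc)
  structure(list(scores = sv$u %*% diag(sv$d, length(sv$d)),
                 loadings = t(sv$v), singular_values = sv$d,
                 explained = sv$d^2 / sum(sv$d^2), center = mu),
            class = "pca_decomposition")
}

#' Participation ratio of a covariance matrix
#'
#' `tr(C)^2 / tr(C^2)`, computed from traces (no eigendecomposition): the
#' effective dimensionality of the eigenspectrum, between 1 (rank one) and
#' the matrix dimension (isotropic).
#'
#' @param C symmetric positive semidefinite matrix.
#' @return scalar participation ratio.
#' @export
participation_ratio <- function(C) {
  sum(diag(C))^2 / sum(C * C)
}

#' First principal angle between two subspaces, in degrees
#'
#' `acos` of the largest singular value of the cross-projection of the two
#' orthonormal bases; 0 for a shared direction, 90 for orthogonal subspaces.
#'
#' @param QA,QB k x N matrices with orthonormal rows spanning the subspaces.
#' @return angle in degrees, in `[0, 90]`.
#' @export
first_principal_angle <- function(QA, QB) {
  QA <- rbind(QA); QB <- rbind(QB)
  s <- svd(QA %*% t(QB))$d
  acos(min(1, max(s))) * 180 / pi
}

#' Between-condition alignment index over the top d principal components
#'
#' The variance of condition A's activity captured by condition B's top `d`
#' principal components, normalized by the variance captured by A's own top
#' `d` components: `sum_i q^i_B C_A q^i_B' / sum_i sigma^i_A`. Equals 1 when
#' the subspaces coincide and approaches 1 as `d` approaches the data
#' dimensionality, hence the 40-unit inclusion rule upstream.
#'
#' @param C_A N x N covariance of condition A's activity.
#' @param Q_B loadings matrix of condition B (rows orthonormal); the top `d`
#'   rows are used.
#' @param d number of components (default 10).
#' @return alignment index in `[0, 1]`.
#' @export
alignment_index <- function(C_A, Q_B, d = 10L) {
  d <- min(d, nrow(rbind(Q_B)))
  Qd <- rbind(Q_B)[seq_len(d), , drop = FALSE]
  num <- sum(diag(Qd %*% C_A %*% t(Qd)))
  ev <- eigen(C_A, symmetric = TRUE, only.values = TRUE)$values
  num / sum(ev[seq_len(d)])
}

# condition covariance of a soft-normalized aligned matrix (over time bins)
activity_covariance <- function(X) stats::cov(X)

#' Observed cross-condition geometry for a pair of aligned matrices
#' @param X_A,X_B T x N soft-normalized trial-mean matrices.
#' @param k subspace dimension for the principal angle (default 1).
#' @param d components for the alignment index (default 10).
#' @param center centre columns before PCA.
#' @return list `angle_deg`, `alignment`, plus each condition's explained
#'   variance fractions and participation ratio.
#' @export
condition_pair_geometry <- function(X_A, X_B, k = 1L, d = 10L, center = TRUE) {
  pa <- pca_decompose(X_A, center); pb <- pca_decompose(X_B, center)
  CA <- activity_covariance(X_A)
  list(angle_deg = first_principal_angle(pa$loadings[seq_len(k), , drop = FALSE],
                                         pb$loadings[seq_len(k), , drop = FALSE]),
       alignment = alignment_index(CA, pb$loadings, d),
       explained_A = pa$explained, explained_B = pb$explained,
       participation_A = participation_ratio(CA),
       participation_B = participation_ratio(activity_covariance(X_B)))
}

# trial-mean PETH matrix (T x N) from a trials x T x N array, soft-normalized
half_mean <- function(arr, idx, soft_c) {
  m <- colMeans(arr[idx, , , drop = FALSE], dims = 1L)
  soft_normalize(m, soft_c)
}

#' Bootstrap prediction of angle/alignment under invariant encoding
#'
#' Per iteration the trials of both conditions are split into random halves;
#' each half's PETHs are averaged across the two conditions with weights
#' inverse to trial counts (so both conditions contribute equally), PCA is
#' run per half, and the subspace angle and alignment index are computed
#' *between the halves*. The spread of the resulting distribution is the
#' finite-data floor: what "perfectly aligned" looks like at this trial
#' count.
#'
#' @param trials_A,trials_B arrays `trials x T x N` of per-trial PETH rates
#'   for the two conditions (>= 2 trials per condition per half, i.e. >= 4
#'   trials each).
#' @param n_boot iterations (default 1000).
#' @param seed integer RNG seed.
#' @param k,d angle subspace dimension and alignment component count.
#' @param soft_c soft-normalization constant.
#' @param center centre columns before PCA.
#' @return data.frame with `angle_deg` and `alignment`, one row per
#'   iteration.
#' @export
bootstrap_invariant_prediction <- function(trials_A, trials_B, n_boot = 1000L,
                                           seed = 1L, k = 1L, d = 10L,
                                           soft_c = 5, center = TRUE) {
  stopifnot(dim(trials_A)[1L] >= 4L, dim(trials_B)[1L] >= 4L)
  set.seed(seed)
  one <- function() {
    ia <- sample(dim(trials_A)[1L]); ib <- sample(dim(trials_B)[1L])
    ha <- list(ia[seq_len(length(ia) %/% 2L)], ia[-seq_len(length(ia) %/% 2L)])
    hb <- list(ib[seq_len(length(ib) %/% 2L)], ib[-seq_len(length(ib) %/% 2L)])
    halves <- lapply(1:2, function(h) {
      # equal-weight average of the two conditions' half trial-means
      m <- (colMeans(trials_A[ha[[h]], , , drop = FALSE], dims = 1L) +
              colMeans(trials_B[hb[[h]], , , drop = FALSE], dims = 1L)) / 2
      soft_normalize(m, soft_c)
    })
    p1 <- pca_decompose(halves[[1L]], center)
    p2 <- pca_decompose(halves[[2L]], center)
    c(first_principal_angle(p1$loadings[seq_len(k), , drop = FALSE],
                            p2$loadings[seq_len(k), , drop = FALSE]),
      alignment_index(activity_covariance(halves[[1L]]), p2$loadings, d))
  }
  res <- t(vapply(seq_len(n_boot), function(i) one(), numeric(2)))
  data.frame(angle_deg = res[, 1L], alignment = res[, 2L])
}

#' Jointly orthonormal projections maximizing per-condition explained
#' variance
#'
#' Finds `V = [V1 V2]` with jointly orthonormal columns maximizing
#' `tr(V1' C1 V1) + tr(V2' C2 V2)` by block coordinate ascent: with one block
#' fixed, the optimum of the other is the top eigenvectors of the covariance
#' projected onto the fixed block's orthogonal complement, so every sweep
#' increases the objective. Restarts guard against local maxima.
#'
#' @param C1,C2 N x N symmetric PSD matrices.
#' @param d1,d2 subspace dimensions (`d1 + d2 <= N`).
#' @param tol relative objective tolerance (default 1e-8).
#' @param max_iter sweep cap per restart.
#' @param restarts random restarts beyond the eigenvector initialization.
#' @return list: `V1` (N x d1), `V2` (N x d2), `objective`, `trace`
#'   (objective per sweep of the winning run), `converged`.
#' @export
orthogonal_projections <- function(C1, C2, d1 = 10L, d2 = 10L, tol = 1e-8,
                                   max_iter = 5000L, restarts = 3L) {
  N <- nrow(C1)
  stopifnot(d1 + d2 <= N, nrow(C2) == N)
  top_evec <- function(C, d) eigen(C, symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
  run <- function(V2) {
    obj <- -Inf; trace <- numeric()
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      P2 <- diag(N) - V2 %*% t(V2)
      V1 <- top_evec(P2 %*% C1 %*% P2, d1)
      P1 <- diag(N) - V1 %*% t(V1)
      V2 <- top_evec(P1 %*% C2 %*% P1, d2)
      new_obj <- sum(diag(t(V1) %*% C1 %*% V1)) + sum(diag(t(V2) %*% C2 %*% V2))
      trace <- c(trace, new_obj)
      if (new_obj - obj <= tol * max(1, abs(new_obj))) {
        obj <- new_obj; converged <- TRUE; break
      }
      obj <- new_obj
    }
    list(V1 = V1, V2 = V2, objective = obj, trace = trace, converged = converged)
  }
  best <- run(top_evec(C2, d2))
  for (r in seq_len(restarts)) {
    V0 <- qr.Q(qr(matrix(stats::rnorm(N * d2), N, d2)))
    cand <- run(V0)
    if (cand$objective > best$objective) best <- cand
  }
  best
}

#' Bootstrap prediction of angle/alignment under orthogonal encoding
#'
#' Per iteration, trials are split into halves. Half 1 is used to find two
#' jointly orthonormal projections maximizing the explained variance of the
#' two objectives (laterality: ipsilateral and contralateral; manuality:
#' ipsilateral + contralateral versus bimanual). Half 2 of each compared
#' condition is then orthogonalized against the *other* condition's learned
#' subspace (its component in that subspace is projected out, keeping its own
#' signal and the residual noise), and the subspace angle and alignment index
#' are computed on these data — what "perfectly orthogonal" looks like at
#' this trial count and noise level. Keeping the residual noise is what makes
#' the prediction a distribution rather than a point mass at 90 degrees / 0;
#' see the methods vignette.
#'
#' @param trials list of `trials x T x N` arrays named by condition
#'   (laterality mode needs ipsilateral + contralateral; manuality all
#'   three).
#' @param mode `"laterality"` or `"manuality"`.
#' @param pair the two conditions compared after projection (defaults:
#'   ipsi/contra for laterality, contralateral/bimanual for manuality).
#' @param n_boot iterations.
#' @param seed integer RNG seed.
#' @param k,d,soft_c,center as in [bootstrap_invariant_prediction()].
#' @param dproj dimension of each learned projection (default `d`, capped at
#'   `N %/% 2`).
#' @param opt_args list overriding [orthogonal_projections()] controls.
#' @return data.frame with `angle_deg` and `alignment` per iteration.
#'   Iterations whose optimizer fails to converge are discarded (error if
#'   more than 10% are).
#' @export
bootstrap_orthogonal_prediction <- function(trials,
                                            mode = c("laterality", "manuality"),
                                            pair = NULL, n_boot = 1000L, seed = 1L,
                                            k = 1L, d = 10L, soft_c = 5,
                                            center = TRUE, dproj = NULL,
                                            opt_args = list()) {
  mode <- match.arg(mode)
  if (is.null(pair))
    pair <- if (mode == "laterality") c("ipsilateral", "contralateral") else
      c("contralateral", "bimanual")
  need <- if (mode == "laterality") c("ipsilateral", "contralateral") else CONDITIONS
  stopifnot(all(need %in% names(trials)))
  N <- dim(trials[[1L]])[3L]
  dproj <- min(dproj %||% d, N %/% 2L)
  oa <- modifyList(list(tol = 1e-8, max_iter = 200L, restarts = 0L), opt_args)
  set.seed(seed)
  split_half <- function(arr) {
    idx <- sample(dim(arr)[1L])
    list(idx[seq_len(length(idx) %/% 2L)], idx[-seq_len(length(idx) %/% 2L)])
  }
  res <- matrix(NA_real_, n_boot, 2L)
  for (i in seq_len(n_boot)) {
    sp <- lapply(trials[need], split_half)
    h1 <- lapply(need, function(cc) half_mean(trials[[cc]], sp[[cc]][[1L]], soft_c))
    names(h1) <- need
    cen <- function(X) if (center) sweep(X, 2L, colMeans(X), "-") else X
    Cs <- lapply(h1, function(X) activity_covariance(X))
    if (mode == "laterality") {
      C1 <- Cs$ipsilateral; C2 <- Cs$contralateral
      vmap <- c(ipsilateral = 1L, contralateral = 2L)
    } else {
      C1 <- Cs$ipsilateral + Cs$contralateral; C2 <- Cs$bimanual
      vmap <- c(ipsilateral = 1L, contralateral = 1L, bimanual = 2L)
    }
    op <- orthogonal_projections(C1, C2, dproj, dproj, tol = oa$tol,
                                 max_iter = oa$max_iter, restarts = oa$restarts)
    if (!op$converged) next
    # orthogonalize each condition against the other's subspace: remove the
    # component in the other block, keep own signal + residual noise
    IN <- diag(N)
    proj <- list(IN - op$V2 %*% t(op$V2), IN - op$V1 %*% t(op$V1))
    Xp <- lapply(pair, function(cc) {
      X2 <- half_mean(trials[[cc]], sp[[cc]][[2L]], soft_c)
      cen(X2) %*% proj[[vmap[[cc]]]]
    })
    pa <- pca_decompose(Xp[[1L]], center = FALSE)  # already centred/projected
    pb <- pca_decompose(Xp[[2L]], center = FALSE)
    res[i, ] <- c(first_principal_angle(pa$loadings[seq_len(k), , drop = FALSE],
                                        pb$loadings[seq_len(k), , drop = FALSE]),
                  alignment_index(stats::cov(Xp[[1L]]), pb$loadings, d))
  }
  ok <- !is.na(res[, 1L])
  if (mean(ok) < 0.9) stop("more than 10% of optimizer iterations failed to converge")
  data.frame(angle_deg = res[ok, 1L], alignment = res[ok, 2L])
}

#' Permutation test for an area difference in deviation from a prediction
#'
#' For each recording, the deviation is the observed statistic minus the
#' median of its bootstrap prediction. Deviations are averaged over the
#' hierarchy (probes, days, mice; conditions enter as replicate rows), the
#' between-area difference of the means is taken, and compared two-sided
#' against the distribution of the same quantity under `n_perm` random
#' reassignments of recording-level area labels.
#'
#' @param stats data.frame with columns `mouse, day, probe, area, observed,
#'   predicted_median` (one row per recording x condition-pair).
#' @param n_perm permutations (default 10000).
#' @param seed integer RNG seed.
#' @return list: `observed_diff`, `p`, `n_perm`, `areas`.
#' @export
area_permutation_difference_test <- function(stats, n_perm = 10000L, seed = 1L) {
  areas <- sort(unique(stats$area))
  if (length(areas) != 2L) stop("need exactly two areas")
  stats$value <- stats$observed - stats$predicted_median
  diff_of <- function(s) {
    g <- lapply(areas, function(a) {
      ha <- hierarchical_average(
        s[s$area == a, c("mouse", "day", "probe", "value")], "grand")
      mean(ha$value)
    })
    g[[1L]] - g[[2L]]
  }
  observed <- diff_of(stats)
  rec_key <- interaction(stats$mouse, stats$day, stats$probe, drop = TRUE)
  rec_area <- tapply(stats$area, rec_key, `[`, 1L)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    s <- stats
    s$area <- sample(rec_area)[as.integer(rec_key)]
    diff_of(s)
  }, numeric(1))
  list(observed_diff = observed, p = mean(abs(perm) >= abs(observed)),
       n_perm = n_perm, areas = areas)
}
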