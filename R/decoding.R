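#' Split a condition's bins into contiguous tuning / training / testing
#' thirds
#'
#' Contiguous chunks (not random bins) so temporal autocorrelation does not
#' leak across sets; sizes differ by at most one. The same split is reused
#' for every limb and dimension of a condition.
#'
#' @param n_bins number of decodable rows.
#' @return list of integer index vectors `tuning`, `training`, `testing` —
#'   pairwise disjoint and jointly exhaustive.
#' @export
split_sets <- function(n_bins) {
  stopifnot(n_bins >= 3L)
  base <- n_bins %/% 3L
  sizes <- rep(base, 3L) + c(n_bins %% 3L >= 1L, n_bins %% 3L >= 2L, FALSE)
  ends <- cumsum(sizes)
  list(tuning = seq_len(ends[1L]),
       training = (ends[1L] + 1L):ends[2L],
       testing = (ends[2L] + 1L):ends[3L])
}

#' Lagged design matrix over binned spikes
#'
#' Row `t` holds every unit's counts from `lag_before_s` before to
#' `lag_after_s` after the decoded bin (at 5 ms: 51 taps per unit), plus the
#' intercept handled downstream. Rows whose window crosses an epoch splice or
#' the data edge are dropped rather than zero-padded.
#'
#' @param binned one condition's [bin_and_slice()] entry (`counts`,
#'   `splices`), or a bins x units matrix (single epoch).
#' @param bin_s bin width (seconds).
#' @param lag_before_s,lag_after_s decoding window extent.
#' @return list: `X` (rows x (units x taps)), `rows` (indices into the
#'   original bins that each design row decodes), `lags` (tap offsets in
#'   bins).
#' @export
lagged_design <- function(binned, bin_s = 0.005, lag_before_s = 0.2,
                          lag_after_s = 0.05) {
  counts <- if (is.list(binned)) binned$counts else binned
  splices <- if (is.list(binned)) binned$splices else 1L
  nb <- nrow(counts); nu <- ncol(counts)
  lags <- seq(-round(lag_before_s / bin_s), round(lag_after_s / bin_s))
  seg_start <- splices
  seg_end <- c(splices[-1L] - 1L, nb)
  seg_of <- rep(seq_along(seg_start), seg_end - seg_start + 1L)
  t_all <- seq_len(nb)
  ok <- t_all + lags[1L] >= seg_start[seg_of] & t_all + lags[length(lags)] <= seg_end[seg_of]
  rows <- t_all[ok]
  X <- matrix(0, length(rows), nu * length(lags))
  for (j in seq_along(lags)) {
    X[, (j - 1L) * nu + seq_len(nu)] <- counts[rows + lags[j], , drop = FALSE]
  }
  list(X = X, rows = rows, lags = lags)
}

# ridge with standardized columns and unpenalized intercept; returns the
# whole lambda path. Uses the primal (p x p) or dual (n x n) eigendecomposed
# normal equations, whichever is smaller.
ridge_path <- function(X, y, lambdas) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  ym <- mean(y)
  yc <- y - ym
  n <- nrow(Xs); p <- ncol(Xs)
  if (p <= n) {
    eg <- eigen(crossprod(Xs), symmetric = TRUE)
    Uty <- crossprod(eg$vectors, crossprod(Xs, yc))
    beta <- vapply(lambdas, function(l)
      as.vector(eg$vectors %*% (Uty / (eg$values + l))), numeric(p))
  } else {
    eg <- eigen(tcrossprod(Xs), symmetric = TRUE)
    Qty <- crossprod(eg$vectors, yc)
    beta <- vapply(lambdas, function(l) {
      alpha <- eg$vectors %*% (Qty / (eg$values + l))
      as.vector(crossprod(Xs, alpha))
    }, numeric(p))
  }
  list(beta = matrix(beta, ncol = length(lambdas)), mu = mu, sd = sdv, ym = ym)
}

ridge_predict <- function(fit, X, j = 1L) {
  Xs <- sweep(sweep(X, 2L, fit$mu, "-"), 2L, fit$sd, "/")
  as.vector(Xs %*% fit$beta[, j]) + fit$ym
}

#' Coefficient of determination
#' @param y observed values; `pred` predictions.
#' @param pred predicted values.
#' @return `1 - SS_res / SS_tot`; 1 for perfect prediction, 0 for predicting
#'   the mean of `y`, negative values allowed.
#' @export
r_squared <- function(y, pred) {
  ok <- !is.na(y) & !is.na(pred)
  y <- y[ok]; pred <- pred[ok]
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Fit a ridge-regularized lagged decoder with grid-searched penalty
#'
#' The penalty `lambda` is chosen by grid search with contiguous k-fold
#' cross-validation over the tuning set (maximizing mean held-out R^2), then
#' the final coefficients are the ridge solution on the training set at the
#' chosen `lambda`. Columns are z-scored on training statistics; the
#' intercept is unpenalized. Rows with missing targets are dropped.
#'
#' @param X_tune,y_tune hyperparameter-tuning design and target.
#' @param X_train,y_train training design and target.
#' @param lambda_grid candidate penalties (default the config grid,
#'   logarithmic 1e-2..1e4).
#' @param n_folds contiguous CV folds (default 5).
#' @return list of class `decoder_model`: `fit` (coefficients and scaling),
#'   `lambda`, `cv_r2` (grid x 1 mean CV R^2), `lambda_grid`.
#' @export
fit_decoder <- function(X_tune, y_tune, X_train, y_train,
                        lambda_grid = default_config()$corr_decode$lambda_grid,
                        n_folds = 5L) {
  keep <- !is.na(y_tune)
  X_tune <- X_tune[keep, , drop = FALSE]; y_tune <- y_tune[keep]
  if (!length(y_tune)) stop("all tuning targets missing")
  cv <- matrix(NA_real_, n_folds, length(lambda_grid))
  fold <- cut(seq_along(y_tune), n_folds, labels = FALSE)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- ridge_path(X_tune[tr, , drop = FALSE], y_tune[tr], lambda_grid)
    for (j in seq_along(lambda_grid))
      cv[f, j] <- r_squared(y_tune[!tr], ridge_predict(fit, X_tune[!tr, , drop = FALSE], j))
  }
  mcv <- colMeans(cv)
  jbest <- which.max(mcv)
  keep <- !is.na(y_train)
  if (!sum(keep)) stop("all training targets missing")
  fit <- ridge_path(X_train[keep, , drop = FALSE], y_train[keep],
                    lambda_grid[jbest])
  structure(list(fit = fit, lambda = lambda_grid[jbest], cv_r2 = mcv,
                 lambda_grid = lambda_grid),
            class = "decoder_model")
}

#' Evaluate a decoder on a testing set
#' @param model a [fit_decoder()] result.
#' @param X_test,y_test testing design and target (disjoint from tuning and
#'   training).
#' @return cross-validated R^2.
#' @export
evaluate_decoder <- function(model, X_test, y_test) {
  r_squared(y_test, ridge_predict(model$fit, X_test))
}

#' Cross-condition generalization of a decoder
#'
#' Applies `model_other` (fit in another condition / to the other limb) to
#' this condition's testing set and expresses the change relative to the
#' within-condition decoder `model_within` on the same rows as a percentage:
#' `(R2_cross - R2_0) / R2_0 * 100`. Zero is perfect generalization; a drop
#' to zero accuracy gives -100%.
#'
#' @param model_other,model_within decoder models.
#' @param X_test,y_test the testing set both models are evaluated on.
#' @return list: `r2_within` (R2_0), `r2_cross`, `delta_pct`.
#' @export
generalize <- function(model_other, model_within, X_test, y_test) {
  r2_0 <- evaluate_decoder(model_within, X_test, y_test)
  r2_x <- evaluate_decoder(model_other, X_test, y_test)
  if (is.na(r2_0) || r2_0 <= 0)
    return(list(r2_within = r2_0, r2_cross = r2_x, delta_pct = NA_real_))
  list(r2_within = r2_0, r2_cross = r2_x,
       delta_pct = (r2_x - r2_0) / r2_0 * 100)
}

#' Bootstrap nulls for perfect and no generalization
#'
#' The testing set is chunked into `n_chunks` contiguous pieces; each
#' iteration permutes the chunks and concatenates the first and second halves
#' into two pseudo-sets, decoded by the *same* within-condition decoder.
#' `mode = "perfect"` decodes each half from its own neural data (one half
#' arbitrarily the within set, the other the cross set); `mode = "none"`
#' decodes the first half's kinematics from the second half's neural data.
#'
#' @param model the within-condition decoder.
#' @param X_test,y_test testing set.
#' @param mode `"perfect"` or `"none"`.
#' @param n_boot iterations (default 1000).
#' @param seed integer RNG seed.
#' @param n_chunks number of chunks (default 20).
#' @return numeric vector of `delta_pct` values (length `n_boot`; iterations
#'   with non-positive reference R^2 give `NA`).
#' @export
bootstrap_generalization_null <- function(model, X_test, y_test,
                                          mode = c("perfect", "none"),
                                          n_boot = 1000L, seed = 1L,
                                          n_chunks = 20L) {
  mode <- match.arg(mode)
  n <- length(y_test)
  stopifnot(n >= 2L * n_chunks)
  chunk <- cut(seq_len(n), n_chunks, labels = FALSE)
  pred_all <- ridge_predict(model$fit, X_test)
  set.seed(seed)
  vapply(seq_len(n_boot), function(i) {
    ord <- sample(n_chunks)
    h1 <- which(chunk %in% ord[seq_len(n_chunks %/% 2L)])
    h2 <- which(chunk %in% ord[-seq_len(n_chunks %/% 2L)])
    if (mode == "perfect") {
      r2_0 <- r_squared(y_test[h1], pred_all[h1])
      r2_x <- r_squared(y_test[h2], pred_all[h2])
    } else {
      m <- min(length(h1), length(h2))
      r2_0 <- r_squared(y_test[h1], pred_all[h1])
      r2_x <- r_squared(y_test[h1][seq_len(m)], pred_all[h2][seq_len(m)])
    }
    if (is.na(r2_0) || r2_0 <= 0) return(NA_real_)
    (r2_x - r2_0) / r2_0 * 100
  }, numeric(1))
}

#' Area permutation test on generalization deviations
#'
#' Identical contract to [area_permutation_difference_test()], applied to
#' per-recording `delta_pct` deviations from the invariant-prediction
#' medians; shares that implementation.
#'
#' @inheritParams area_permutation_difference_test
#' @return see [area_permutation_difference_test()].
#' @export
area_generalization_permutation_test <- function(stats, n_perm = 10000L, seed = 1L) {
  area_permutation_difference_test(stats, n_perm = n_perm, seed = seed)
}
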