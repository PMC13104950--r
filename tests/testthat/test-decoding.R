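test_that("split_sets: thirds, remainder rule, partition property", {
  s <- split_sets(3000)
  expect_equal(lengths(s), c(tuning = 1000L, training = 1000L, testing = 1000L))
  s1 <- split_sets(3001)
  expect_true(max(lengths(s1)) - min(lengths(s1)) <= 1L)
  all_idx <- unname(unlist(s1))
  expect_equal(sort(all_idx), 1:3001)                       # exhaustive
  expect_equal(anyDuplicated(all_idx), 0L)                  # disjoint
})

test_that("lagged design: tap layout and splice handling", {
  counts <- matrix(seq_len(40), 20, 2)   # 20 bins, 2 units
  b <- list(counts = counts, splices = c(1L, 11L))
  d <- lagged_design(b, bin_s = 0.005, lag_before_s = 0.01, lag_after_s = 0.005)
  expect_equal(d$lags, -2:1)
  expect_equal(ncol(d$X), 2L * 4L)
  # valid rows: within each 10-bin segment, need 2 before and 1 after
  expect_equal(d$rows, c(3:9, 13:19))
  # row decoding bin t holds counts[t + lag]
  r1 <- d$X[1, ]                          # t = 3
  expect_equal(r1, c(counts[1, ], counts[2, ], counts[3, ], counts[4, ]))
})

test_that("R^2 anchors: perfect, mean, worse-than-mean", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_lt(r_squared(y, rep(10, 4)), 0)
})

test_that("ridge: shrinkage monotonicity and training-R^2 monotone in lambda", {
  set.seed(71)
  n <- 300; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- X %*% beta + rnorm(n, 0, 0.5)
  lambdas <- 10^seq(-2, 4, length.out = 13)
  fit <- popcode:::ridge_path(X, y, lambdas)
  norms <- sqrt(colSums(fit$beta^2))
  expect_true(all(diff(norms) < 0))                # ||beta|| shrinks with lambda
  r2_train <- vapply(seq_along(lambdas), function(j)
    r_squared(y, popcode:::ridge_predict(fit, X, j)), numeric(1))
  expect_true(all(diff(r2_train) <= 1e-10))        # non-increasing
  # lambda -> Inf: prediction approaches the training mean
  fit_big <- popcode:::ridge_path(X, y, 1e8)
  expect_lt(max(abs(popcode:::ridge_predict(fit_big, X) - mean(y))), 1e-3)
})

test_that("primal and dual ridge paths agree", {
  set.seed(72)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- rnorm(80)
  lam <- c(0.5, 10)
  f1 <- popcode:::ridge_path(X, y, lam)                       # primal (p < n)
  f2 <- popcode:::ridge_path(X[1:25, ], y[1:25], lam)         # dual (p > n)
  # dual route checked against direct solve on the standardized problem
  Xs <- scale(X[1:25, ]); ys <- y[1:25] - mean(y[1:25])
  bdirect <- solve(crossprod(Xs) + diag(0.5, 30), crossprod(Xs, ys))
  expect_equal(unname(f2$beta[, 1]), as.vector(bdirect), tolerance = 1e-8)
})

test_that("duplicated unit columns shrink symmetrically (algebraic oracle)", {
  set.seed(73)
  n <- 240
  x <- rpois(n, 3)
  z <- rpois(n, 2)
  y <- 0.8 * x + rnorm(n, 0, 0.3)
  lam <- 1
  f2 <- popcode:::ridge_path(cbind(x, z, x), y, lam)
  # the duplicates carry identical weight
  expect_equal(f2$beta[1, 1], f2$beta[3, 1], tolerance = 1e-10)
  # duplicating the only column at penalty lambda is algebraically identical
  # to the single column at penalty lambda/2: predictions equal to 1e-8
  fd <- popcode:::ridge_path(cbind(x, x), y, lam)
  fs <- popcode:::ridge_path(matrix(x), y, lam / 2)
  expect_equal(popcode:::ridge_predict(fd, cbind(x, x)),
               popcode:::ridge_predict(fs, matrix(x)), tolerance = 1e-8)
})

test_that("decoder recovers a noiseless linear readout (R^2 >= 0.99)", {
  sc <- make_scenario("linear_decode", seed = 5, snr = Inf)
  cd <- default_config()$corr_decode
  counts <- popcode:::bin_spikes(sc$recording, 0.005)
  des <- lagged_design(counts, 0.005, cd$lag_before_s, cd$lag_after_s)
  y <- sc$target[des$rows]
  ok <- !is.na(y)
  X <- des$X[ok, , drop = FALSE]; y <- y[ok]
  sp <- split_sets(nrow(X))
  m <- fit_decoder(X[sp$tuning, ], y[sp$tuning], X[sp$training, ],
                   y[sp$training], lambda_grid = c(0.01, 1, 100), n_folds = 3)
  expect_gte(evaluate_decoder(m, X[sp$testing, ], y[sp$testing]), 0.99)
  # coefficient recovery: cosine similarity to the true taps
  # (design columns are grouped by lag, units within lag)
  bhat <- m$fit$beta[, 1] / m$fit$sd
  bt <- unlist(lapply(seq_along(sc$truth$decode_lags), function(j)
    sc$truth$decode_taps[, j]))
  cosang <- sum(bhat * bt) / sqrt(sum(bhat^2) * sum(bt^2))
  expect_gte(cosang, 0.95)
})

test_that("pure-noise targets are not decodable", {
  set.seed(74)
  r2 <- vapply(1:10, function(i) {
    X <- matrix(rpois(900 * 8, 1), 900, 8)
    y <- rnorm(900)
    sp <- split_sets(900)
    m <- fit_decoder(X[sp$tuning, ], y[sp$tuning], X[sp$training, ],
                     y[sp$training], lambda_grid = c(1, 100), n_folds = 3)
    evaluate_decoder(m, X[sp$testing, ], y[sp$testing])
  }, numeric(1))
  expect_lt(max(r2), 0.05)
})

test_that("generalization anchors are exact", {
  set.seed(75)
  X <- matrix(rpois(600 * 6, 2), 600, 6)
  y <- X %*% rnorm(6) * 0.2 + rnorm(600, 0, 0.2)
  sp <- split_sets(600)
  m <- fit_decoder(X[sp$tuning, ], y[sp$tuning], X[sp$training, ],
                   y[sp$training], lambda_grid = c(0.1, 10), n_folds = 3)
  g_self <- generalize(m, m, X[sp$testing, ], y[sp$testing])
  expect_equal(g_self$delta_pct, 0)            # self-generalization = 0%
  expect_equal(g_self$r2_within, g_self$r2_cross)
  # a cross decoder predicting the testing mean has R^2 exactly 0 -> -100%
  m0 <- m
  m0$fit$beta[] <- 0
  m0$fit$ym <- mean(y[sp$testing])
  g0 <- generalize(m0, m, X[sp$testing, ], y[sp$testing])
  expect_equal(g0$r2_cross, 0)
  expect_equal(g0$delta_pct, (0 - g0$r2_within) / g0$r2_within * 100)
  expect_equal(g0$delta_pct, -100)
})

test_that("generalization nulls: perfect near 0%, none near -100%", {
  sc <- make_scenario("linear_decode", seed = 6, snr = 20)
  cd <- default_config()$corr_decode
  counts <- popcode:::bin_spikes(sc$recording, 0.005)
  des <- lagged_design(counts, 0.005, cd$lag_before_s, cd$lag_after_s)
  y <- sc$target[des$rows]
  ok <- !is.na(y)
  X <- des$X[ok, , drop = FALSE]; y <- y[ok]
  sp <- split_sets(nrow(X))
  m <- fit_decoder(X[sp$tuning, ], y[sp$tuning], X[sp$training, ],
                   y[sp$training], lambda_grid = c(0.1, 10), n_folds = 3)
  pf <- bootstrap_generalization_null(m, X[sp$testing, ], y[sp$testing],
                                      "perfect", n_boot = 150, seed = 1)
  nn <- bootstrap_generalization_null(m, X[sp$testing, ], y[sp$testing],
                                      "none", n_boot = 150, seed = 2)
  expect_lt(abs(median(pf, na.rm = TRUE)), 5)
  expect_lt(median(nn, na.rm = TRUE), -80)
})

test_that("area generalization permutation test shares the deviation contract", {
  set.seed(76)
  st <- data.frame(mouse = paste0("m", 1:12), day = "d", probe = "p",
                   area = rep(c("flM1", "LOM"), each = 6),
                   observed = c(rnorm(6, -40), rnorm(6, -10)),
                   predicted_median = -5)
  r1 <- area_generalization_permutation_test(st, n_perm = 200, seed = 3)
  r2 <- area_permutation_difference_test(st, n_perm = 200, seed = 3)
  expect_identical(r1, r2)
  expect_lt(r1$p, 0.05)  # planted 30-point difference, 6 recordings/group
})
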