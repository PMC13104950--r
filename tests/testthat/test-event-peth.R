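test_that("PETH binning conventions: 100 bins, half-open edges, rate scaling", {
  # single spike exactly at onset falls in the first post-onset bin
  p <- build_peth(c(5.0), onsets = 5.0, duration = 20)
  expect_equal(ncol(p$counts), 100L)          # [-1, 1] s at 20 ms
  hit <- which(p$counts[1, ] == 1)
  expect_equal(p$bin_centers[hit], 0.01)      # first bin after onset
  expect_equal(sum(p$counts), 1)
  expect_equal(peth_mean(p)[hit], 50)         # 1 spike / 0.02 s
  # a spike just before onset lands in the last pre-onset bin
  p2 <- build_peth(c(5.0 - 1e-9), onsets = 5.0, duration = 20)
  expect_equal(p2$bin_centers[which(p2$counts[1, ] == 1)], -0.01)
  expect_error(build_peth(c(1), numeric(0), 10), "at least one event")
})

test_that("PETH total counts equal direct interval counting (oracle)", {
  set.seed(31)
  st <- sort(runif(2000, 0, 100))
  onsets <- seq(5, 95, by = 5)
  p <- build_peth(st, onsets, duration = 100)
  oracle <- sum(vapply(onsets, function(e)
    sum(st >= e - 1 & st < e + 1), numeric(1)))
  expect_equal(sum(p$counts), oracle)
})

test_that("homogeneous Poisson PETH mean is flat at the true rate", {
  set.seed(32)
  dur <- 2000
  st <- sort(runif(rpois(1, 10 * dur), 0, dur))
  onsets <- runif(200, 1, dur - 1)
  p <- build_peth(st, onsets, dur)
  m <- peth_mean(p)
  se <- sqrt(10 / (0.02 * length(onsets)))
  expect_true(all(abs(m - 10) < 4 * se))
  expect_lt(abs(mean(m) - 10), 3 * se / sqrt(10))  # bins correlated-free here
})

test_that("cross-cycle oromanual epochs are masked per trial", {
  # event at 10 s starts its own epoch [10, 10.5]; the previous cycle's
  # epoch [9.2, 9.5] must be masked inside the aligned window
  oro <- data.frame(start_s = c(10, 9.2), end_s = c(10.5, 9.5))
  p <- build_peth(c(9.9), onsets = 10, duration = 20, oro_epochs = oro)
  masked <- !p$mask[1, ]
  ctr <- p$bin_centers
  inside_other <- ctr + 10 > 9.2 & ctr + 10 < 9.5
  expect_true(all(masked[inside_other]))
  expect_equal(sum(masked), sum(inside_other))  # epoch edges align with bins
  # its own epoch (starting at the onset) is not masked
  expect_false(any(masked[ctr > 0 & ctr < 0.5]))
  # events near the recording edge mask out-of-range bins instead of erroring
  p2 <- build_peth(c(0.5), onsets = 0.5, duration = 20)
  expect_true(all(!p2$mask[1, p2$bin_centers < -0.5]))
  expect_true(all(is.na(p2$rate[1, p2$bin_centers < -0.5])))
})

test_that("bootstrap significance: conventions and calibration basics", {
  # zero-spike unit -> p = 1
  r <- bootstrap_significance(numeric(0), onsets = c(5, 6), duration = 20,
                              n_boot = 100, seed = 1)
  expect_equal(r$p, 1)
  # smallest attainable p is 0 (counting definition, strict >)
  set.seed(33)
  dur <- 300
  ev <- seq(10, 290, by = 10)
  u <- gained_train(8, ev, gain = 8, width = 0.2, duration = dur, seed = 34)
  r2 <- bootstrap_significance(u, ev, dur, n_boot = 200, seed = 2)
  expect_equal(r2$p, 0)
  expect_equal(length(r2$sham_max), 200L)
})

test_that("strong planted response is detected with high power", {
  # 5x gain in a 200 ms window at onset, 30 events, 10 Hz baseline:
  # p < 0.001 in >= 95% of replicates (scaled: 40 replicates, 1000 draws)
  set.seed(35)
  dur <- 400
  ev <- seq(6, 394, by = 13)[1:30]
  hits <- vapply(1:40, function(i) {
    u <- gained_train(10, ev, gain = 5, width = 0.2, duration = dur,
                      seed = 100 + i)
    bootstrap_significance(u, ev, dur, n_boot = 1000, seed = i)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null sham statistics are exchangeable with the real statistic", {
  # The max-rate statistic is discrete (resolution 1/(n_events x 20 ms)), so
  # under the strict-> counting convention ties push null p-values below
  # uniform: exact KS uniformity is unattainable by construction. The
  # property that must (and does) hold is exchangeability: the real maximum
  # is distributed like the sham maxima, and P(sham > real) = P(real > sham).
  set.seed(36)
  dur <- 600
  reals <- numeric(200); sham1 <- numeric(200); pgt <- plt <- numeric(200)
  for (i in 1:200) {
    u <- poisson_train(5, dur, seed = 400 + i)
    ev <- runif(20, 1, dur - 1)
    b <- bootstrap_significance(u, ev, dur, n_boot = 200, seed = 500 + i)
    reals[i] <- b$real_max
    sham1[i] <- b$sham_max[1]
    pgt[i] <- mean(b$sham_max > b$real_max)     # the reported p
    plt[i] <- mean(b$sham_max < b$real_max)
  }
  # identical marginal distributions of real and sham maxima
  ks <- suppressWarnings(stats::ks.test(reals, sham1))
  expect_gt(ks$p.value, 0.01)
  # symmetry of the exceedance probabilities (tie mass excluded from both)
  expect_lt(abs(mean(pgt) - mean(plt)), 3 * stats::sd(pgt - plt) / sqrt(200))
  # the strict-> p-value never exceeds its >=-counting counterpart
  expect_true(all(pgt + plt <= 1))
})

test_that("baseline subtraction matches hand arithmetic on a 3-trial toy", {
  # trial counts chosen by hand; 20 ms bins, baseline window [-1, -0.2] s
  # trial 1: 2 spikes in every baseline bin (rate 100), 4 spikes in one
  # post-onset bin; trial 2: silent baseline; trial 3: 1 spike per baseline bin
  bw <- 0.02
  onsets <- c(100, 200, 300)
  mk_trial <- function(on, per_bin, post) {
    base_bins <- seq(on - 1, on - 0.2 - bw, by = bw)
    st <- unlist(lapply(base_bins, function(b)
      if (per_bin > 0) b + bw * seq_len(per_bin) / (per_bin + 1) else numeric(0)))
    c(st, rep(on + 0.01, post))
  }
  st <- sort(c(mk_trial(100, 2, 4), mk_trial(200, 0, 4), mk_trial(300, 1, 4)))
  p <- build_peth(st, onsets, duration = 400)
  pb <- baseline_subtract(p)
  # baselines: 100 Hz, 0 Hz, 50 Hz
  expect_equal(pb$baseline, c(100, 0, 50))
  post_bin <- which(pb$bin_centers == 0.01)
  expect_equal(pb$rate[, post_bin], 4 / bw - c(100, 0, 50))
  # constant-rate unit: trial-mean ~ 0 after subtraction within each trial's
  # baseline window by construction
  expect_equal(mean(pb$rate[1, pb$bin_centers < -0.2]), 0)
})

test_that("fully-masked baseline drops the trial with a warning", {
  # prior oromanual epoch covering the whole baseline window of trial 1
  oro <- data.frame(start_s = c(8.9, 10), end_s = c(9.9, 10.5))
  expect_warning(
    pb <- baseline_subtract(build_peth(c(10.2), onsets = c(10, 15),
                                       duration = 30, oro_epochs = oro)),
    "fully-masked baseline")
  expect_equal(pb$n_trials, 1L)
})

test_that("baseline subtraction commutes with averaging on unmasked trials", {
  set.seed(37)
  st <- sort(runif(3000, 0, 200))
  onsets <- seq(10, 190, by = 9)
  p <- build_peth(st, onsets, 200)
  pb <- baseline_subtract(p)
  lhs <- peth_mean(pb)                       # subtract, then average
  rhs <- peth_mean(p) - mean(pb$baseline)    # average, then subtract mean base
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("z-scoring: guarded division, scale invariance, hand-checked s.d.", {
  # all-zero PETH stays all-zero
  p0 <- build_peth(numeric(0) + 1e9, onsets = c(5, 6), duration = 20)
  p0$counts[] <- 0; p0$rate[] <- 0
  p0$baseline_subtracted <- TRUE; p0$baseline <- c(0, 0)
  z0 <- zscore_peth(p0)
  expect_true(all(z0$rate == 0))
  # scale invariance: scaling rates by 10 leaves the z-scored PETH unchanged
  set.seed(38)
  st <- sort(runif(4000, 0, 300))
  p <- baseline_subtract(build_peth(st, seq(5, 295, by = 10), 300))
  z1 <- zscore_peth(p)
  p10 <- p; p10$rate <- p$rate * 10
  z10 <- zscore_peth(p10)
  expect_equal(z1$rate, z10$rate, tolerance = 1e-12)
  # dispersion is the s.d. of the trial-mean PETH over the full window
  expect_equal(z1$rate, p$rate / sd(peth_mean(p)), tolerance = 1e-12)
})

test_that("responsiveness categories form the exact 8-way partition", {
  fl <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
              c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
              c(FALSE, TRUE, TRUE), c(FALSE, FALSE, FALSE), c(NA, TRUE, TRUE))
  colnames(fl) <- CONDITIONS
  r <- categorize_responsiveness(fl)
  expect_equal(r$category[1:8],
               c("all", "ipsi_only", "contra_only", "bi_only", "ipsi_contra",
                 "ipsi_bi", "contra_bi", "none"))
  expect_true(is.na(r$category[9]))                 # missing condition excluded
  expect_equal(sum(r$proportions), 1)
  expect_equal(unname(r$proportions["none"]), 1 / 8)
  expect_equal(sum(r$responder_proportions), 1)     # none excluded from Venn
  expect_false("none" %in% names(r$responder_proportions))
})

test_that("planted contra-only responders are recovered in proportion", {
  # 300 units, 30% with a contra-only response; recovered within 5 points
  set.seed(39)
  dur <- 350
  ev <- list(ipsilateral = seq(5, 110, by = 3.6),
             contralateral = seq(120, 225, by = 3.6),
             bimanual = seq(235, 340, by = 3.6))
  n_units <- 300
  planted <- runif(n_units) < 0.3
  flags <- matrix(NA, n_units, 3, dimnames = list(NULL, CONDITIONS))
  for (i in seq_len(n_units)) {
    u <- if (planted[i])
      gained_train(8, ev$contralateral, gain = 6, width = 0.2, duration = dur,
                   seed = 600 + i)
    else poisson_train(8, dur, seed = 600 + i)
    for (cc in CONDITIONS)  # draws scaled down; threshold = 1/n_boot
      flags[i, cc] <- bootstrap_significance(u, ev[[cc]], dur, n_boot = 400,
                                             seed = 700 + i)$p < 0.0025
  }
  r <- categorize_responsiveness(flags)
  expect_lt(abs(r$proportions[["contra_only"]] - mean(planted)), 0.05)
})
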