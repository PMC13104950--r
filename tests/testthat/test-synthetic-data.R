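test_that("noiseless kinematics equal the piecewise model and stated onsets", {
  cfg <- behavior_config(cycles_per_condition = 3, noise_sd_mm = 0)
  beh <- generate_kinematics(cfg, seed = 7)
  # computed distances equal the true traces exactly (no embedding error)
  ok <- !is.na(beh$kinematics$d_left_nose)
  expect_equal(beh$kinematics$d_left_nose[ok], beh$truth$d_true$left[ok],
               tolerance = 1e-9)
  # oromanual plateaus closer to the nose than holding plateaus, per session
  for (h in c("left", "right")) {
    d <- beh$truth$d_true[[h]]
    st <- beh$truth[[h]]
    expect_lt(mean(d[st == "oromanual_ingestion"]),
              mean(d[st == "holding_chewing"]))
  }
  # ground-truth transports: onset is the 5% departure from holding; the
  # noiseless trace at the stored onset is within 5% of the plateau gap
  tr <- beh$events[beh$events$kind == "transport" & beh$events$hand == "left", ]
  idx <- findInterval(tr$onset_s, beh$kinematics$time_s)
  d_at <- beh$truth$d_true$left[idx]
  hold <- cfg$hold_dist_mm
  expect_true(all(abs(d_at - hold) < 0.15 * hold))
})

test_that("generator is deterministic under a fixed seed", {
  cfg <- behavior_config(cycles_per_condition = 2)
  b1 <- generate_kinematics(cfg, seed = 11)
  b2 <- generate_kinematics(cfg, seed = 11)
  expect_equal(b1$kinematics$d_left_nose, b2$kinematics$d_left_nose,
               tolerance = 1e-9)
  expect_identical(b1$events, b2$events)
  s1 <- generate_spikes(b1$kinematics, b1$events[b1$events$kind == "transport", ],
                        population_config(n_units = 6), seed = 3)
  s2 <- generate_spikes(b2$kinematics, b2$events[b2$events$kind == "transport", ],
                        population_config(n_units = 6), seed = 3)
  for (u in 1:6)
    expect_identical(s1$recording$units[[u]]$spike_times,
                     s2$recording$units[[u]]$spike_times)
  b3 <- generate_kinematics(cfg, seed = 12)
  expect_false(identical(b1$events$onset_s, b3$events$onset_s))
})

test_that("schedule longer than an explicit duration errors", {
  expect_error(generate_kinematics(
    behavior_config(cycles_per_condition = 10, duration_s = 5), seed = 1),
    "schedule needs")
})

test_that("blocked hand is flagged missing in at least half its frames", {
  beh <- generate_kinematics(behavior_config(cycles_per_condition = 4), seed = 2)
  blocks <- beh$truth$blocks
  for (b in seq_len(nrow(blocks))) {
    if (blocks$hand[b] == "both") next
    unused <- setdiff(c("left", "right"), blocks$hand[b])
    idx <- beh$kinematics$time_s >= blocks$start_s[b] &
      beh$kinematics$time_s < blocks$end_s[b]
    vflag <- beh$kinematics[[paste0(substr(unused, 1, 1), "_valid")]][idx]
    expect_gte(mean(!vflag), 0.5)
  }
})

test_that("zero gain gives empirical rates at baseline (Poisson CI)", {
  beh <- generate_kinematics(behavior_config(
    cycles_per_condition = 2, schedule = "both", duration_s = 600), seed = 5)
  ev <- beh$events[beh$events$kind == "transport", ]
  cfg <- population_config(n_units = 20, gain_hz = 0, noise_gain_hz = 0,
                           baseline_mean_hz = 10)
  sp <- generate_spikes(beh$kinematics, ev, cfg, seed = 6)
  dur <- sp$recording$duration
  for (u in seq_len(20)) {
    n <- length(sp$recording$units[[u]]$spike_times)
    lam <- sp$truth$baseline_hz[u] * dur
    expect_lt(abs(n - lam), 3 * sqrt(lam) + 1e-9)
  }
})

test_that("total spike count scales linearly with duration", {
  counts <- vapply(c(200, 400, 800), function(dur) {
    beh <- generate_kinematics(behavior_config(
      cycles_per_condition = 2, schedule = "both", duration_s = dur), seed = 5)
    sp <- generate_spikes(beh$kinematics,
                          beh$events[beh$events$kind == "transport", ],
                          population_config(n_units = 10, gain_hz = 0,
                                            noise_gain_hz = 0,
                                            baseline_mean_hz = 8), seed = 9)
    sum(vapply(sp$recording$units, function(u) length(u$spike_times), numeric(1)))
  }, numeric(1))
  # doubling duration doubles counts within Poisson error (~3 sd)
  for (i in 1:2) {
    ratio <- counts[i + 1] / counts[i]
    se <- sqrt(1 / counts[i + 1] + 1 / counts[i]) * 2
    expect_lt(abs(ratio - 2), 3 * 2 * se + 0.02)
  }
})

test_that("fully_dependent loadings are pairwise orthogonal by construction", {
  beh <- generate_kinematics(behavior_config(cycles_per_condition = 2), seed = 1)
  sp <- generate_spikes(beh$kinematics,
                        beh$events[beh$events$kind == "transport", ],
                        population_config(n_units = 30, mode = "fully_dependent"),
                        seed = 2)
  W <- sp$truth$loadings
  for (pr in list(c("ipsilateral", "contralateral"),
                  c("ipsilateral", "bimanual"),
                  c("contralateral", "bimanual")))
    expect_lt(max(abs(crossprod(W[[pr[1]]], W[[pr[2]]]))), 1e-10)
  # invariant mode: identical loadings
  spi <- generate_spikes(beh$kinematics,
                         beh$events[beh$events$kind == "transport", ],
                         population_config(n_units = 30, mode = "invariant"),
                         seed = 2)
  expect_identical(spi$truth$loadings$ipsilateral,
                   spi$truth$loadings$bimanual)
})

test_that("invariant-mode PETH differences shrink as event count grows", {
  max_diff <- vapply(c(6, 24), function(cyc) {
    beh <- generate_kinematics(behavior_config(cycles_per_condition = cyc),
                               seed = 3)
    ev <- beh$events[beh$events$kind == "transport", ]
    sp <- generate_spikes(beh$kinematics, ev,
                          population_config(n_units = 40, mode = "invariant"),
                          seed = 4)
    peths <- build_peth_set(sp$recording, ev)
    # population-mean PETH per condition; compare ipsi vs contra
    pm <- function(cc) rowMeans(vapply(peths, function(pl) peth_mean(pl[[cc]]),
                                       numeric(100)))
    max(abs(pm("ipsilateral") - pm("contralateral")), na.rm = TRUE)
  }, numeric(1))
  expect_lt(max_diff[2], max_diff[1])
})

test_that("scenarios store the stated ground truth", {
  sn <- make_scenario("null", seed = 2)
  expect_null(sn$truth$loadings)  # no modulation parameter stored
  sl <- make_scenario("LOM_like", seed = 2, n_units = 12,
                      cycles_per_condition = 2)
  expect_equal(sl$truth$mode, "invariant")
  expect_equal(sl$truth$profile, "sustained")
  sf <- make_scenario("flM1_like", seed = 2, n_units = 12,
                      cycles_per_condition = 2)
  expect_equal(sf$truth$profile, "transient")
  sd_ <- make_scenario("linear_decode", seed = 2)
  expect_false(is.null(sd_$truth$decode_taps))
  expect_equal(dim(sd_$truth$decode_taps),
               c(n_units(sd_$recording), length(sd_$truth$decode_lags)))
  expect_error(make_scenario("unknown"), "arg")
})

test_that("scenario bundles write through pipeline_io", {
  b <- make_scenario("null", seed = 3)
  d <- withr::local_tempdir()
  write_bundle(b, d)
  expect_true(all(file.exists(file.path(
    d, c("spikes.csv", "spikes.json", "kinematics.csv", "events.csv",
         "ground_truth.json")))))
  rec <- read_spikes(file.path(d, "spikes.csv"))
  expect_equal(n_units(rec), n_units(b$recording))
})

test_that("linear_kinematic encoding taps are recoverable by OLS (oracle)", {
  # Tap identifiability needs lagged features that are not collinear, so this
  # oracle runs in a rough-tracking world (12 mm positional noise -> white
  # variation at the frame rate), with 10 ms tap spacing, a strong kinematic
  # drive against a high baseline (small relative Poisson noise), and a long
  # two-hand session. Regression bins = one kinematic frame (5 ms) so the
  # generator's frame->rate mapping is reproduced exactly.
  beh <- generate_kinematics(behavior_config(cycles_per_condition = 45,
                                             schedule = c("left", "right"),
                                             noise_sd_mm = 12),
                             seed = 8)
  ev <- beh$events[beh$events$kind == "transport", ]
  lags <- seq(-0.05, 0, by = 0.01)
  cfg <- population_config(n_units = 6, gain_hz = 0, noise_gain_hz = 0,
                           baseline_mean_hz = 300, baseline_shape = 100,
                           encoding = "linear_kinematic", kin_gain_hz = 120,
                           kin_lags_s = lags)
  sp <- generate_spikes(beh$kinematics, ev, cfg, seed = 9)
  bin <- 0.005
  fr <- attr(beh$kinematics, "frame_rate")
  counts <- popcode:::bin_spikes(sp$recording, bin)
  feats <- scale(cbind(beh$kinematics$d_left_nose, beh$kinematics$d_right_nose))
  feats[is.na(feats)] <- 0
  nb <- nrow(counts)
  tgrid <- (seq_len(nb) - 0.5) * bin
  fidx <- pmin(pmax(floor(tgrid * fr) + 1L, 1L), nrow(feats))
  X <- do.call(cbind, lapply(round(lags * fr), function(l) {
    src <- pmin(pmax(fidx + l, 1L), nrow(feats))
    feats[src, ]
  }))
  rel_rmse <- vapply(seq_len(6), function(u) {
    y <- counts[, u] / bin
    bhat <- stats::lm.fit(cbind(1, X), y)$coefficients[-1]
    # X columns are (feat within lag); truth taps are [lag, feat]
    bt <- as.vector(t(sp$truth$taps[u, , ]))
    sqrt(mean((bhat - bt)^2)) / sqrt(mean(bt^2))
  }, numeric(1))
  expect_lt(stats::median(rel_rmse), 0.10)
})
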