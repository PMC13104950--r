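test_that("distance computation: 3-4-5 triangle, propagation, degenerate geometry", {
  k <- compute_distances(kin_frame(l = c(0, 0, 0), r = c(1, 1, 1), n = c(3, 4, 0)))
  expect_equal(k$d_left_nose, 5)
  # missing left hand: left and both-nose missing, right computed
  k <- compute_distances(kin_frame(l = c(0, 0, 0), r = c(0, 0, 1), n = c(3, 4, 0),
                                   l_valid = FALSE))
  expect_true(is.na(k$d_left_nose))
  expect_true(is.na(k$d_both_nose))
  expect_equal(k$d_right_nose, sqrt(9 + 16 + 1))
  expect_true(is.na(k$d_hand_hand))
  # coincident hands: hand-hand 0 and both-nose equals left-nose
  k <- compute_distances(kin_frame(l = c(1, 2, 2), r = c(1, 2, 2), n = c(0, 0, 0)))
  expect_equal(k$d_hand_hand, 0)
  expect_equal(k$d_both_nose, k$d_left_nose)
  expect_equal(k$d_left_nose, 3)
})

test_that("combined ethogram follows the seven-state truth table", {
  H <- "holding_chewing"; O <- "oromanual_ingestion"; X <- "other"
  expect_equal(combine_hand_states(c(H, O, X, H, O, X), c(X, X, X, H, O, O)),
               c("left_holding", "left_oromanual", "both_other",
                 "both_holding", "both_oromanual", "right_oromanual"))
  # mixed holding/oromanual pairs map to both_oromanual (documented choice)
  expect_equal(combine_hand_states(c(H, O), c(O, H)),
               rep("both_oromanual", 2))
  # property: pure function, order-insensitive across random sequences
  set.seed(1)
  for (i in 1:20) {
    l <- sample(c(H, O, X), 50, TRUE); r <- sample(c(H, O, X), 50, TRUE)
    comb <- combine_hand_states(l, r)
    expect_equal(comb, vapply(seq_along(l), function(j)
      combine_hand_states(l[j], r[j]), character(1)))
  }
})

test_that("segmentation recovers a constructed two-plateau trace exactly", {
  # stationary plateaus at 12 mm (holding) and 3 mm (oromanual), instant drop
  nfr <- 120
  d <- c(rep(12, 60), rep(3, 60))
  dir <- c(1, 0, 0)
  kin <- data.frame(time_s = (0:(nfr - 1)) / 200,
                    lx = d, ly = 0, lz = 0, rx = 25, ry = 0, rz = 0,
                    nx = 0, ny = 0, nz = 0,
                    l_valid = TRUE, r_valid = TRUE, n_valid = TRUE)
  kin <- compute_distances(kin)
  cfg <- default_config()
  cfg$ethogram$speed_smooth_frames <- 1L
  th <- list(left = c(oromanual = 7, holding = 16),
             right = c(oromanual = 7, holding = 16))
  et <- segment_ethogram(kin, th, cfg)
  expect_equal(et$left, rep(c("holding_chewing", "oromanual_ingestion"),
                            each = 60))
  # the resting right hand is holding-band? no: 25 mm is beyond the band
  expect_true(all(et$right == "other"))
  expect_equal(unique(et$combined[1:59]), "left_holding")
})

test_that("inverted thresholds error; short glitches are absorbed", {
  kin <- compute_distances(kin_frame(l = c(12, 0, 0), r = c(25, 0, 0),
                                     n = c(0, 0, 0), nframes = 30))
  expect_error(segment_ethogram(kin, list(left = c(oromanual = 10, holding = 5),
                                          right = c(oromanual = 5, holding = 10))),
               "inverted")
  # 30-frame toy: 3-frame dip below the oromanual threshold inside a holding
  # run, min run 10 -> absorbed into holding (hand-enumerated expectation)
  d <- rep(12, 30); d[15:17] <- 3
  st <- rep("holding_chewing", 30); st[15:17] <- "oromanual_ingestion"
  merged <- popcode:::merge_short_runs(st, 10L)
  expect_equal(merged, rep("holding_chewing", 30))
  # but a run of 10 survives
  st2 <- rep("holding_chewing", 30); st2[11:20] <- "oromanual_ingestion"
  expect_equal(popcode:::merge_short_runs(st2, 10L), st2)
})

test_that("segmentation is invariant to a constant added to distances and thresholds", {
  # noiseless so the radial shift leaves hand speeds untouched
  beh <- generate_kinematics(behavior_config(cycles_per_condition = 3,
                                             noise_sd_mm = 0), seed = 5)
  kin <- beh$kinematics
  th <- beh$truth$thresholds
  e1 <- segment_ethogram(kin, th)
  shift <- 40
  kin2 <- kin
  # shift hand positions radially away from the nose by `shift` mm
  for (h in c("l", "r")) {
    cols <- paste0(h, c("x", "y", "z"))
    p <- as.matrix(kin[, cols])
    n <- as.matrix(kin[, c("nx", "ny", "nz")])
    dvec <- p - n
    dn <- sqrt(rowSums(dvec^2))
    kin2[, cols] <- n + dvec * (dn + shift) / dn
  }
  kin2 <- compute_distances(kin2)
  th2 <- lapply(th, function(x) x + shift)
  e2 <- segment_ethogram(kin2, th2)
  expect_identical(e1$left, e2$left)
  expect_identical(e1$right, e2$right)
  expect_identical(e1$combined, e2$combined)
})

test_that("transition fits recover exact sigmoid and exponential parameters", {
  t <- seq(0, 0.8, by = 0.005)
  # sigmoid drop 12 -> 3, midpoint 0.4, scale such that rise time is 80 ms
  s <- 0.08 / (2 * log(19))
  y <- 3 + (12 - 3) / (1 + exp((t - 0.4) / s))
  f <- fit_transition(t, y, "sigmoid")
  expect_false(f$low_confidence)
  expect_lt(abs(f$params[["m"]] - 0.4), 0.005)       # midpoint within 1 frame
  expect_lt(abs(f$onset_s - (0.4 - s * log(19))), 0.002)
  expect_lt(f$gof, 1e-6)
  # exponential rise 3 -> 12, tau = 150 ms
  y2 <- 12 + (3 - 12) * exp(-t / 0.15)
  f2 <- fit_transition(t, y2, "exponential")
  expect_lt(abs(f2$params[["tau"]] - 0.15) / 0.15, 0.01)  # tau within 1%
  expect_lt(abs(f2$onset_s - 0.15 * log(1 / 0.95)), 0.002)
  expect_error(fit_transition(t[1:5], y[1:5], "sigmoid"), "8 valid frames")
})

test_that("noisy sigmoid onsets are recovered within 10 ms (Monte-Carlo)", {
  # 1 kHz-equivalent sampling, noise s.d. 5% of the asymptote gap, 500 fits
  set.seed(13)
  n_sim <- 500
  t <- seq(0, 0.6, by = 0.001)
  s <- 0.08 / (2 * log(19))
  gap <- 9
  err <- vapply(seq_len(n_sim), function(i) {
    m <- runif(1, 0.25, 0.35)
    y <- 3 + gap / (1 + exp((t - m) / s)) + rnorm(length(t), 0, 0.05 * gap)
    f <- fit_transition(t, y, "sigmoid")
    abs(f$onset_s - (m - s * log(19)))
  }, numeric(1))
  expect_gte(mean(err < 0.010), 0.95)
})

test_that("transport detection labels conditions and applies exclusions", {
  # constructed per-hand state sequences at 200 Hz
  H <- "holding_chewing"; O <- "oromanual_ingestion"; X <- "other"
  fr <- 200
  mk_etho <- function(left, right) {
    n <- length(left)
    structure(list(time_s = (0:(n - 1)) / fr, left = left, right = right,
                   combined = combine_hand_states(left, right),
                   frame_rate = fr), class = "ethogram")
  }
  flat_kin <- function(n) {
    k <- data.frame(time_s = (0:(n - 1)) / fr, lx = 10, ly = 0, lz = 0,
                    rx = 10, ry = 0, rz = 0, nx = 0, ny = 0, nz = 0,
                    l_valid = TRUE, r_valid = TRUE, n_valid = TRUE)
    compute_distances(k)
  }
  # left holding -> oromanual on a right-hemisphere probe => contralateral
  et <- mk_etho(c(rep(H, 100), rep(O, 100)), rep(X, 200))
  tr <- detect_transports(et, flat_kin(200), "right")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$condition, "contralateral")
  expect_false(tr$excluded)
  # same on a left-hemisphere probe => ipsilateral
  expect_equal(detect_transports(et, flat_kin(200), "left")$condition,
               "ipsilateral")
  # uni-to-bimanual: left already oromanual when right transitions => excluded
  et2 <- mk_etho(c(rep(H, 60), rep(O, 240)),
                 c(rep(H, 200), rep(O, 100)))
  tr2 <- detect_transports(et2, flat_kin(300), "left")
  inc2 <- tr2[!tr2$excluded, ]
  expect_equal(nrow(inc2), 1L)  # only the left-hand event survives
  expect_true("uni_to_bimanual" %in% tr2$reason[tr2$excluded])
  # entry from other (armbar rest) => excluded
  et3 <- mk_etho(c(rep(X, 150), rep(O, 100)), rep(X, 250))
  tr3 <- detect_transports(et3, flat_kin(250), "left")
  expect_true(all(tr3$excluded) && all(tr3$reason == "from_other"))
  # simultaneous bilateral holding -> oromanual => one bimanual event
  et4 <- mk_etho(c(rep(H, 100), rep(O, 100)), c(rep(H, 102), rep(O, 98)))
  tr4 <- detect_transports(et4, flat_kin(200), "left")
  expect_equal(nrow(tr4), 1L)
  expect_equal(tr4$condition, "bimanual")
})

test_that("generator sessions: all transports detected with matched conditions", {
  beh <- generate_kinematics(behavior_config(cycles_per_condition = 4), seed = 21)
  st <- stage_events(beh$kinematics, "left")
  truth <- beh$events[beh$events$kind == "transport", ]
  inc <- st$transports[!st$transports$excluded, ]
  expect_equal(nrow(inc), nrow(truth))
  expect_equal(as.vector(table(inc$condition)),
               as.vector(table(truth$condition)))
  err <- abs(sort(inc$onset_s) - sort(truth$onset_s))
  expect_lt(max(err), 0.010)
  # per-hand state sequences match the ground truth on most frames
  expect_gt(mean(st$ethogram$left == beh$truth$left), 0.9)
  expect_gt(mean(st$ethogram$right == beh$truth$right), 0.9)
})
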