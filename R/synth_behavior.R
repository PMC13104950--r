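#' Configuration for the synthetic behavior generator
#'
#' The generator emulates head-fixed rodent food handling: alternating
#' holding/chewing and oromanual/ingestion epochs, with sigmoidal hand-nose
#' distance drops at transports-to-mouth and exponential rises at
#' lowering-from-mouth. Food is held closer to the mouth during
#' oromanual/ingestion than during holding/chewing, so
#' `oro_dist_mm < hold_dist_mm` is enforced.
#'
#' @param frame_rate_hz sampling rate of the kinematics (default 200, the
#'   analysis rate).
#' @param cycles_per_condition number of holding->oromanual cycles per
#'   schedule block.
#' @param schedule character vector of block hand usage, in order; entries in
#'   `c("left","right","both")`.
#' @param hold_dist_mm,hold_sd_mm holding-plateau hand-nose distance mean and
#'   between-plateau s.d.
#' @param oro_dist_mm,oro_sd_mm oromanual-plateau distance mean and s.d.
#' @param rest_dist_mm hand-nose distance of a resting / blocked hand.
#' @param sigmoid_rise_ms transport duration (5%-to-95% of the sigmoid).
#' @param exp_tau_ms exponential time constant of lowering-from-mouth.
#' @param hold_dur_s,oro_dur_s mean plateau durations; `dur_jitter` is their
#'   lognormal s.d. fraction.
#' @param noise_sd_mm per-frame positional noise s.d. (on the hand-nose
#'   distance scale).
#' @param bimanual_lag_sd_s s.d. of the inter-hand lag at bimanual
#'   transports (kept well inside the 200 ms synchrony window).
#' @param occlusion_frac fraction of frames of the unused hand flagged
#'   missing during unimanual blocks (>= 0.5 emulates real occlusion).
#' @param block_gap_s rest gap between schedule blocks.
#' @param duration_s total session length; `NULL` means "as long as the
#'   schedule needs". A schedule longer than an explicit duration is an
#'   error.
#' @param hemisphere hemisphere used to attach condition labels to
#'   ground-truth events.
#' @return list of class `behavior_config`.
#' @export
behavior_config <- function(frame_rate_hz = 200, cycles_per_condition = 20,
                            schedule = c("left", "right", "both"),
                            hold_dist_mm = 12, hold_sd_mm = 1,
                            oro_dist_mm = 3, oro_sd_mm = 0.5,
                            rest_dist_mm = 25,
                            sigmoid_rise_ms = 80, exp_tau_ms = 150,
                            hold_dur_s = 2.0, oro_dur_s = 1.5, dur_jitter = 0.15,
                            noise_sd_mm = 0.25, bimanual_lag_sd_s = 0.02,
                            occlusion_frac = 0.7, block_gap_s = 2,
                            duration_s = NULL, hemisphere = "left") {
  stopifnot(oro_dist_mm < hold_dist_mm, frame_rate_hz > 0,
            cycles_per_condition >= 1, all(schedule %in% c("left", "right", "both")),
            sigmoid_rise_ms > 0, exp_tau_ms > 0, hold_dur_s > 0, oro_dur_s > 0)
  structure(as.list(environment()), class = "behavior_config")
}

# unit direction vectors from nose to each hand (arbitrary but fixed geometry)
HAND_DIR <- list(left = c(-0.5, -0.7, -0.5) / sqrt(0.99),
                 right = c(0.5, -0.7, -0.5) / sqrt(0.99))

#' Generate synthetic food-handling kinematics with ground truth
#'
#' Builds per-hand hand-nose distance traces from the piecewise plateau +
#' sigmoid/exponential model of [behavior_config()], embeds them as 3D marker
#' positions (nose at the origin, each hand along a fixed direction), and
#' returns the kinematics together with the true transition events and the
#' true per-frame ethogram. The unused hand in unimanual blocks is flagged
#' missing in occlusion bouts covering about `occlusion_frac` of frames.
#'
#' @param config a [behavior_config()].
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return list with:
#' * `kinematics` — data.frame in the [read_kinematics()] schema with derived
#'   distances already attached,
#' * `events` — ground-truth transitions (`onset_s`, `hand`, `condition`,
#'   `kind` in `c("transport","lowering")`),
#' * `truth` — list with per-hand and combined true state sequences and the
#'   true thresholds (`oromanual`, `holding`) that separate the plateaus,
#' * `config` — the config used.
#' @export
generate_kinematics <- function(config, seed = 1L) {
  cfg <- config
  set.seed(seed)
  fr <- cfg$frame_rate_hz
  dt <- 1 / fr
  rise <- cfg$sigmoid_rise_ms / 1000
  tau <- cfg$exp_tau_ms / 1000
  lower_dur <- tau * log(40)  # run the exponential to 2.5% residual, then snap

  jit <- function(mu) mu * exp(stats::rnorm(1, 0, cfg$dur_jitter))

  # -- lay out segments per hand ------------------------------------------
  # each hand gets a vector of (time, level) "knots" plus transition records
  seg <- list(left = list(), right = list())
  events <- list()
  blocks <- list()
  t_cur <- cfg$block_gap_s
  for (b in seq_along(cfg$schedule)) {
    hand_use <- cfg$schedule[b]
    hands <- if (hand_use == "both") c("left", "right") else hand_use
    # entry: rest -> holding (sigmoid drop; excluded-kind transition, not a transport)
    t_entry <- t_cur
    lead <- 0.6
    t <- t_entry + lead
    block_start <- t_entry
    for (cyc in seq_len(cfg$cycles_per_condition)) {
      hold_lvl <- stats::rnorm(1, cfg$hold_dist_mm, cfg$hold_sd_mm)
      oro_lvl <- stats::rnorm(1, cfg$oro_dist_mm, cfg$oro_sd_mm)
      hold_end <- t + jit(cfg$hold_dur_s)
      lags <- if (hand_use == "both")
        stats::setNames(c(0, abs(stats::rnorm(1, 0, cfg$bimanual_lag_sd_s))),
                        sample(c("left", "right"))) else
        stats::setNames(0, hands)
      oro_start <- hold_end + rise
      oro_end <- oro_start + jit(cfg$oro_dur_s)
      for (h in hands) {
        seg[[h]][[length(seg[[h]]) + 1L]] <- list(
          hold_start = t, transport_on = hold_end + lags[[h]],
          oro_start = oro_start + lags[[h]], oro_end = oro_end,
          lower_end = oro_end + lower_dur,
          hold_lvl = hold_lvl + stats::rnorm(1, 0, 0.2),
          oro_lvl = oro_lvl + stats::rnorm(1, 0, 0.1))
      }
      events[[length(events) + 1L]] <- data.frame(
        onset_s = hold_end + min(lags), hand = hand_use,
        condition = resolve_condition(hand_use, cfg$hemisphere),
        kind = "transport")
      events[[length(events) + 1L]] <- data.frame(
        onset_s = oro_end + tau * log(1 / 0.95), hand = hand_use,
        condition = resolve_condition(hand_use, cfg$hemisphere),
        kind = "lowering")
      t <- oro_end + lower_dur
    }
    blocks[[b]] <- data.frame(hand = hand_use, start_s = block_start,
                              end_s = t + 0.4)
    t_cur <- t + 0.4 + cfg$block_gap_s
  }
  needed <- t_cur
  duration <- cfg$duration_s %||% needed
  if (needed > duration + 1e-9)
    stop(sprintf("schedule needs %.1f s but duration_s is %.1f s", needed, duration))

  times <- seq(0, duration - dt / 2, by = dt)
  nfr <- length(times)

  # -- evaluate the piecewise model per hand ------------------------------
  s_mid <- rise / (2 * log(19))  # sigmoid scale: 5%-95% in `rise`
  eval_hand <- function(segs) {
    d <- rep(cfg$rest_dist_mm, nfr)
    state <- rep("other", nfr)
    oro_thr <- (cfg$hold_dist_mm + cfg$oro_dist_mm) / 2
    for (sg in segs) {
      # entry into holding handled as instantaneous fill from previous value:
      idx_hold <- times >= sg$hold_start & times < sg$transport_on
      d[idx_hold] <- sg$hold_lvl
      state[idx_hold] <- "holding_chewing"
      # transport: sigmoid drop, evaluated with generous tails
      m <- sg$transport_on + rise / 2
      idx_tr <- times >= sg$transport_on - 0.6 * rise & times < sg$oro_start + 0.6 * rise
      tt <- times[idx_tr]
      d[idx_tr] <- sg$oro_lvl + (sg$hold_lvl - sg$oro_lvl) / (1 + exp((tt - m) / s_mid))
      idx_oro <- times >= sg$oro_start & times < sg$oro_end
      d[idx_oro] <- sg$oro_lvl
      # lowering: exponential rise back to the *next* holding level (approx:
      # rise toward this cycle's holding level, snap at 2.5% residual)
      idx_lo <- times >= sg$oro_end & times < sg$lower_end
      tt <- times[idx_lo]
      d[idx_lo] <- sg$hold_lvl + (sg$oro_lvl - sg$hold_lvl) * exp(-(tt - sg$oro_end) / tau)
      # truth states: moving frames are "other" unless already below the
      # oromanual threshold (the tail of the sigmoid / start of the rise)
      moving <- times >= sg$transport_on & times < sg$oro_start
      state[moving] <- ifelse(d[moving] < oro_thr, "oromanual_ingestion", "other")
      state[idx_oro] <- "oromanual_ingestion"
      state[idx_lo] <- ifelse(d[idx_lo] < oro_thr, "oromanual_ingestion", "other")
    }
    list(d = d, state = state)
  }
  traces <- list(left = eval_hand(seg$left), right = eval_hand(seg$right))

  # -- validity / occlusion ------------------------------------------------
  valid <- list(left = rep(TRUE, nfr), right = rep(TRUE, nfr))
  for (b in seq_along(cfg$schedule)) {
    if (cfg$schedule[b] == "both") next
    unused <- setdiff(c("left", "right"), cfg$schedule[b])
    idx <- which(times >= blocks[[b]]$start_s & times < blocks[[b]]$end_s)
    if (cfg$occlusion_frac > 0 && length(idx)) {
      # occlusion bouts: alternating exponential dwell times with mean
      # occluded bout 0.5 s and visible bout scaled for the target fraction
      p_occl <- cfg$occlusion_frac
      mean_occl <- 0.5
      mean_vis <- mean_occl * (1 - p_occl) / p_occl
      total <- length(idx) * dt
      occl_start <- stats::runif(1) < p_occl
      dwell <- numeric(0); state <- logical(0); acc <- 0; s <- occl_start
      while (acc < total) {
        d <- stats::rexp(1, 1 / (if (s) mean_occl else mean_vis))
        dwell <- c(dwell, d); state <- c(state, s)
        acc <- acc + d; s <- !s
      }
      bout <- rep(state, times = pmax(1, round(dwell / dt)))[seq_along(idx)]
      bout[is.na(bout)] <- s
      valid[[unused]][idx] <- !bout
      traces[[unused]]$state[idx] <- "other"
    }
  }

  # -- embed as 3D positions ----------------------------------------------
  noise <- function(n) matrix(stats::rnorm(3 * n, 0, cfg$noise_sd_mm / sqrt(3)), n, 3)
  nose <- noise(nfr) * 0.3
  pos <- lapply(c(left = "left", right = "right"), function(h)
    nose + traces[[h]]$d %o% HAND_DIR[[h]] + noise(nfr))
  kin <- data.frame(time_s = times,
                    lx = pos$left[, 1], ly = pos$left[, 2], lz = pos$left[, 3],
                    rx = pos$right[, 1], ry = pos$right[, 2], rz = pos$right[, 3],
                    nx = nose[, 1], ny = nose[, 2], nz = nose[, 3],
                    l_valid = valid$left, r_valid = valid$right,
                    n_valid = rep(TRUE, nfr))
  kin <- compute_distances(kin)

  ev <- do.call(rbind, events)
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  oro_thr <- (cfg$hold_dist_mm + cfg$oro_dist_mm) / 2
  hold_thr <- cfg$hold_dist_mm + 0.5 * (cfg$hold_dist_mm - cfg$oro_dist_mm)
  thresholds <- list(left = c(oromanual = oro_thr, holding = hold_thr),
                     right = c(oromanual = oro_thr, holding = hold_thr))
  # ground-truth states = ideal segmentation of the noiseless embedding
  # (thresholds + true speed, no smoothing needed): a noiseless session
  # segmented with these thresholds reproduces the truth exactly
  kin_true <- data.frame(time_s = times,
                         lx = traces$left$d * HAND_DIR$left[1],
                         ly = traces$left$d * HAND_DIR$left[2],
                         lz = traces$left$d * HAND_DIR$left[3],
                         rx = traces$right$d * HAND_DIR$right[1],
                         ry = traces$right$d * HAND_DIR$right[2],
                         rz = traces$right$d * HAND_DIR$right[3],
                         nx = 0, ny = 0, nz = 0,
                         l_valid = TRUE, r_valid = TRUE,
                         n_valid = TRUE)
  cfg_true <- default_config()
  cfg_true$ethogram$speed_smooth_frames <- 1L
  etho_true <- segment_ethogram(compute_distances(kin_true), thresholds,
                                cfg_true)
  truth <- list(left = etho_true$left, right = etho_true$right,
                combined = etho_true$combined,
                time_s = times,
                thresholds = thresholds,
                blocks = do.call(rbind, blocks),
                d_true = list(left = traces$left$d, right = traces$right$d),
                plateau_states = list(left = traces$left$state,
                                      right = traces$right$state))
  list(kinematics = kin, events = ev, truth = truth, config = cfg)
}
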