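HAND_STATES <- c("holding_chewing", "oromanual_ingestion", "other")
COMBINED_STATES <- c("left_holding", "left_oromanual", "right_holding",
                     "right_oromanual", "both_holding", "both_oromanual",
                     "both_other")

#' Combine two per-hand state sequences into the seven-state ethogram
#'
#' Deterministic truth table: a hand in holding/chewing or
#' oromanual/ingestion while the other hand is "other" gives the four
#' single-hand states; matching non-other states give "both_holding" /
#' "both_oromanual"; two "other" hands give "both_other". The mixed pair
#' (one hand holding, the other oromanual — brief around staggered bimanual
#' transports) maps to "both_oromanual": food at the mouth dominates.
#'
#' @param left,right character vectors over
#'   `c("holding_chewing","oromanual_ingestion","other")`.
#' @return character vector of combined states.
#' @export
combine_hand_states <- function(left, right) {
  stopifnot(length(left) == length(right),
            all(left %in% HAND_STATES), all(right %in% HAND_STATES))
  out <- character(length(left))
  lo <- left == "other"; ro <- right == "other"
  lh <- left == "holding_chewing"; rh <- right == "holding_chewing"
  lm <- left == "oromanual_ingestion"; rm_ <- right == "oromanual_ingestion"
  out[lo & ro] <- "both_other"
  out[lh & ro] <- "left_holding"
  out[lm & ro] <- "left_oromanual"
  out[lo & rh] <- "right_holding"
  out[lo & rm_] <- "right_oromanual"
  out[lh & rh] <- "both_holding"
  out[lm & rm_] <- "both_oromanual"
  out[(lh & rm_) | (lm & rh)] <- "both_oromanual"  # mixed pair, see above
  out
}

# merge state runs shorter than min_run into their neighbours (longer
# neighbour wins; leading/trailing short runs merge inward)
merge_short_runs <- function(states, min_run) {
  if (min_run <= 1L || !length(states)) return(states)
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1L) return(states)
    short <- which(r$lengths < min_run)
    if (!length(short)) return(states)
    i <- short[which.min(r$lengths[short])]
    if (i == 1L) {
      r$values[1L] <- r$values[2L]
    } else if (i == length(r$lengths)) {
      r$values[i] <- r$values[i - 1L]
    } else if (r$lengths[i - 1L] >= r$lengths[i + 1L]) {
      r$values[i] <- r$values[i - 1L]
    } else {
      r$values[i] <- r$values[i + 1L]
    }
    states <- inverse.rle(r)
  }
}

# centred moving-average smoothed speed (mm/s) of a 3D trajectory; NA where
# any sample in the window is missing
smoothed_speed <- function(pos, time_s, window) {
  sm <- apply(pos, 2, function(x) {
    if (window <= 1L) return(x)
    stats::filter(x, rep(1 / window, window), sides = 2)
  })
  sm <- matrix(sm, ncol = 3L)
  v <- sqrt(rowSums(diff(sm)^2)) / diff(time_s)
  c(v[1L], v)  # pad first frame
}

#' Segment kinematics into the per-hand and combined ethograms
#'
#' Per hand and frame: oromanual/ingestion when the hand-nose distance is
#' below the oromanual threshold; holding/chewing when it lies in the
#' `[oromanual, holding)` band *and* the hand is stationary (smoothed speed
#' below `config$ethogram$speed_threshold_mm_s`); "other" otherwise,
#' including occluded frames. State runs shorter than
#' `config$ethogram$min_run_frames` are merged into their neighbours before
#' the two per-hand sequences are combined via [combine_hand_states()].
#'
#' @param kin kinematics with derived distances ([compute_distances()]).
#' @param thresholds list with elements `left` and `right`, each
#'   `c(oromanual =, holding =)` in mm (oromanual < holding), or `NULL` to
#'   derive defaults with [suggest_thresholds()].
#' @param config configuration list.
#' @return object of class `ethogram`: list with `time_s`, `left`, `right`,
#'   `combined` state vectors, the `thresholds` used and the `frame_rate`.
#' @export
segment_ethogram <- function(kin, thresholds = NULL, config = default_config()) {
  cfg <- config$ethogram
  if (is.null(thresholds)) thresholds <- suggest_thresholds(kin)
  for (h in c("left", "right")) {
    th <- thresholds[[h]]
    if (!(th[["oromanual"]] < th[["holding"]]))
      stop("inverted thresholds for ", h, " hand")
  }
  hand_state <- function(d, pos, valid, th) {
    spd <- smoothed_speed(pos, kin$time_s, cfg$speed_smooth_frames)
    st <- rep("other", length(d))
    stationary <- !is.na(spd) & spd < cfg$speed_threshold_mm_s
    st[!is.na(d) & d < th[["oromanual"]]] <- "oromanual_ingestion"
    st[!is.na(d) & d >= th[["oromanual"]] & d < th[["holding"]] & stationary] <-
      "holding_chewing"
    st[!valid] <- "other"
    merge_short_runs(st, cfg$min_run_frames)
  }
  left <- hand_state(kin$d_left_nose, as.matrix(kin[, c("lx", "ly", "lz")]),
                     kin$l_valid, thresholds$left)
  right <- hand_state(kin$d_right_nose, as.matrix(kin[, c("rx", "ry", "rz")]),
                      kin$r_valid, thresholds$right)
  structure(list(time_s = kin$time_s, left = left, right = right,
                 combined = combine_hand_states(left, right),
                 thresholds = thresholds,
                 frame_rate = attr(kin, "frame_rate")),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram: %d frames @ %.0f Hz>\n", length(x$time_s), x$frame_rate))
  print(table(x$combined))
  invisible(x)
}

#' Default per-hand thresholds from the bimodal distance histogram
#'
#' The oromanual/holding boundary defaults to the midpoint between the two
#' lowest-distance modes of the hand-nose distance density; the holding/other
#' boundary to the holding mode plus half the oromanual-holding mode gap
#' (capped at the midpoint to any higher rest-position mode). Intended as a
#' reproducible default for synthetic data; real sessions take manual
#' overrides.
#'
#' @param kin kinematics with derived distances.
#' @return list `left`/`right`, each `c(oromanual=, holding=)` in mm.
#' @export
suggest_thresholds <- function(kin) {
  one <- function(d) {
    d <- d[!is.na(d)]
    # nrd0 bandwidth: wide enough that within-plateau jitter does not split
    # a mode, narrow enough to separate oromanual / holding / rest clusters
    den <- stats::density(d, bw = "nrd0", n = 512)
    y <- den$y
    pk <- which(diff(sign(diff(y))) == -2) + 1L
    pk <- pk[y[pk] > 0.05 * max(y)]           # ignore negligible bumps
    modes <- sort(den$x[pk])
    if (length(modes) < 2L) modes <- stats::quantile(d, c(0.25, 0.75))
    oro <- mean(modes[1:2])
    hold <- modes[2] + 0.5 * (modes[2] - modes[1])
    if (length(modes) >= 3L) hold <- min(hold, mean(modes[2:3]))
    c(oromanual = unname(oro), holding = unname(hold))
  }
  list(left = one(kin$d_left_nose), right = one(kin$d_right_nose))
}

#' Fit a transition model function to a distance-trace segment
#'
#' Sigmoids model rising transitions of the hand-nose distance trace of the
#' moving hand around transports-to-mouth (a sigmoidal drop) and all other
#' rising states; exponentials model lowering-from-mouth. The refined onset
#' is the time the fitted model departs its pre-transition asymptote by
#' `onset_fraction` of the asymptote gap (default 5%).
#'
#' @param time_s,value segment of the trace spanning the threshold crossing
#'   plus margins; at least 8 valid frames.
#' @param kind `"sigmoid"` or `"exponential"`.
#' @param onset_fraction departure fraction defining onset and end.
#' @return list with `kind`, `params`, `onset_s`, `end_s`, `gof` (residual
#'   variance fraction, 0 = perfect), `low_confidence`.
#' @details Non-convergence falls back to the mid-value crossing time with
#'   `low_confidence = TRUE`.
#' @export
fit_transition <- function(time_s, value, kind = c("sigmoid", "exponential"),
                           onset_fraction = 0.05) {
  kind <- match.arg(kind)
  ok <- !is.na(value)
  t <- time_s[ok]; y <- value[ok]
  if (length(y) < 8L) stop("need at least 8 valid frames to fit a transition")
  n <- length(y)
  a1 <- mean(y[seq_len(max(2L, floor(n * 0.2)))])
  a2 <- mean(y[seq(n - max(2L, floor(n * 0.2)) + 1L, n)])
  tss <- sum((y - mean(y))^2)
  mid_cross <- t[which.min(abs(y - (a1 + a2) / 2))]
  p <- onset_fraction
  fallback <- list(kind = kind, params = c(a1 = a1, a2 = a2),
                   onset_s = mid_cross, end_s = mid_cross,
                   gof = 1, low_confidence = TRUE)
  # port can report "singular convergence" on (near-)perfect data; accept
  # such fits when the residual variance fraction is tiny
  accept <- function(fit) {
    if (is.null(fit)) return(FALSE)
    tss == 0 || sum(stats::resid(fit)^2) / tss < 0.2
  }
  if (kind == "sigmoid") {
    # scale start from the 25%-75% crossing times, plus coarser fallbacks;
    # keep the best-RSS accepted fit (port can stall in a degenerate
    # step-function optimum from a bad scale start)
    t25 <- t[which.min(abs(y - (0.75 * a1 + 0.25 * a2)))]
    t75 <- t[which.min(abs(y - (0.25 * a1 + 0.75 * a2)))]
    s_starts <- unique(pmax(abs(t75 - t25) / (2 * log(3)),
                            c(1e-3, diff(range(t)) / c(10, 40))))
    fit <- NULL; best_rss <- Inf
    for (s0 in s_starts) {
      f0 <- tryCatch(suppressWarnings(
        stats::nls(y ~ a2 + (a1 - a2) / (1 + exp((t - m) / s)),
                   start = list(a1 = a1, a2 = a2, m = mid_cross, s = s0),
                   algorithm = "port", lower = c(-Inf, -Inf, min(t) - 1, 1e-5),
                   control = stats::nls.control(warnOnly = TRUE))),
        error = function(e) NULL)
      if (!is.null(f0)) {
        rss <- sum(stats::resid(f0)^2)
        if (rss < best_rss) { fit <- f0; best_rss <- rss }
      }
    }
    if (!accept(fit)) return(fallback)
    cf <- stats::coef(fit)
    lag <- cf[["s"]] * log((1 - p) / p)
    list(kind = kind, params = cf,
         onset_s = unname(cf[["m"]] - lag), end_s = unname(cf[["m"]] + lag),
         gof = if (tss > 0) sum(stats::resid(fit)^2) / tss else 0,
         low_confidence = FALSE)
  } else {
    t0 <- t[1L]
    fit <- tryCatch(suppressWarnings(
      stats::nls(y ~ A + (S - A) * exp(-(t - t0) / tau),
                 start = list(S = y[1L], A = a2, tau = diff(range(t)) / 3),
                 algorithm = "port", lower = c(-Inf, -Inf, 1e-5),
                 control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!accept(fit)) return(fallback)
    cf <- stats::coef(fit)
    list(kind = kind, params = c(cf, t0 = t0),
         onset_s = unname(t0 + cf[["tau"]] * log(1 / (1 - p))),
         end_s = unname(t0 + cf[["tau"]] * log(1 / p)),
         gof = if (tss > 0) sum(stats::resid(fit)^2) / tss else 0,
         low_confidence = FALSE)
  }
}

#' Detect condition-labeled transport-to-mouth events
#'
#' Scans the per-hand ethograms for entries into oromanual/ingestion. Only
#' holding/chewing -> oromanual/ingestion transitions of matching handedness
#' are retained as transports; uni-to-bimanual transports, hand swaps and
#' entries from "other" (e.g. hands resting on the armbar) are emitted with
#' `excluded = TRUE` and a reason. A bimanual transport requires both hands
#' to transition within `config$ethogram$synchrony_window_s`. Onsets are
#' refined by sigmoid fits to the falling hand-nose distance
#' ([fit_transition()]); for bimanual events the earlier refined onset is
#' used.
#'
#' @param etho an [segment_ethogram()] result.
#' @param kin kinematics with derived distances (for onset refinement).
#' @param hemisphere recorded hemisphere; resolves hand -> condition.
#' @param config configuration list.
#' @return data.frame with columns `onset_s`, `crossing_s`, `hand`,
#'   `condition`, `kind`, `excluded`, `reason`, `low_confidence`.
#' @export
detect_transports <- function(etho, kin, hemisphere, config = default_config()) {
  cfg <- config$ethogram
  tt <- etho$time_s
  # the state a transition comes *from*: the most recent non-"other" state
  # within a short lookback, so the brief moving gap between holding and the
  # oromanual threshold crossing does not mask the holding origin. Hands that
  # were genuinely resting ("other" throughout the lookback) stay "other".
  lookback <- max(1L, round(0.5 * etho$frame_rate))
  entries <- function(states) {
    i <- which(states[-1L] == "oromanual_ingestion" &
                 states[-length(states)] != "oromanual_ingestion") + 1L
    prev <- vapply(i, function(k) {
      back <- states[max(1L, k - lookback):(k - 1L)]
      nz <- back[back != "other"]
      if (length(nz)) nz[length(nz)] else "other"
    }, character(1))
    data.frame(idx = i, t = tt[i], prev = prev)
  }
  exits <- function(states) {
    i <- which(states[-1L] != "oromanual_ingestion" &
                 states[-length(states)] == "oromanual_ingestion") + 1L
    tt[i]
  }
  ent <- list(left = entries(etho$left), right = entries(etho$right))
  ext <- list(left = exits(etho$left), right = exits(etho$right))
  win <- cfg$synchrony_window_s

  refine <- function(hand, t_cross) {
    d <- if (hand == "left") kin$d_left_nose else kin$d_right_nose
    seg <- which(tt >= t_cross - cfg$fit_margin_s & tt <= t_cross + cfg$fit_margin_s)
    if (sum(!is.na(d[seg])) < 8L)
      return(list(onset_s = t_cross, low_confidence = TRUE))
    f <- fit_transition(tt[seg], d[seg], "sigmoid", cfg$onset_fraction)
    on <- f$onset_s
    if (is.na(on) || abs(on - t_cross) > cfg$fit_margin_s)
      return(list(onset_s = t_cross, low_confidence = TRUE))
    list(onset_s = on, low_confidence = f$low_confidence)
  }

  state_at <- function(states, t) states[max(1L, findInterval(t, tt))]
  used <- list(left = rep(FALSE, nrow(ent$left)), right = rep(FALSE, nrow(ent$right)))
  rows <- list()
  add <- function(onset, cross, hand, excl, reason, lowc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      onset_s = onset, crossing_s = cross, hand = hand,
      condition = resolve_condition(hand, hemisphere), kind = "transport",
      excluded = excl, reason = reason, low_confidence = lowc)
  }

  # pair up bimanual candidates first
  for (i in seq_len(nrow(ent$left))) {
    tl <- ent$left$t[i]
    j <- which(!used$right & abs(ent$right$t - tl) <= win)
    if (length(j)) {
      j <- j[which.min(abs(ent$right$t[j] - tl))]
      used$left[i] <- TRUE; used$right[j] <- TRUE
      prevs <- c(ent$left$prev[i], ent$right$prev[j])
      if (all(prevs == "holding_chewing")) {
        rl <- refine("left", tl); rr <- refine("right", ent$right$t[j])
        add(min(rl$onset_s, rr$onset_s), min(tl, ent$right$t[j]), "both",
            FALSE, "", rl$low_confidence || rr$low_confidence)
      } else {
        add(min(tl, ent$right$t[j]), min(tl, ent$right$t[j]), "both",
            TRUE, "from_other", TRUE)
      }
    }
  }
  # remaining single-hand entries
  for (hand in c("left", "right")) {
    other <- if (hand == "left") "right" else "left"
    e <- ent[[hand]]
    for (i in which(!used[[hand]])) {
      tc <- e$t[i]
      if (e$prev[i] != "holding_chewing") {
        add(tc, tc, hand, TRUE, "from_other", TRUE)
      } else if (state_at(etho[[other]], tc) == "oromanual_ingestion") {
        add(tc, tc, hand, TRUE, "uni_to_bimanual", TRUE)
      } else if (any(abs(ext[[other]] - tc) <= win)) {
        add(tc, tc, hand, TRUE, "hand_swap", TRUE)
      } else {
        r <- refine(hand, tc)
        add(r$onset_s, tc, hand, FALSE, "", r$low_confidence)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(), crossing_s = numeric(), hand = character(),
               condition = character(), kind = character(), excluded = logical(),
               reason = character(), low_confidence = logical())
  out[order(out$onset_s), , drop = FALSE]
}

#' Contiguous oromanual/ingestion epochs from the combined ethogram
#' @param etho an ethogram.
#' @return data.frame `start_s`, `end_s` (end exclusive), one row per epoch
#'   in which at least one hand is in oromanual/ingestion.
#' @export
oromanual_epochs <- function(etho) {
  oro <- etho$combined %in% c("left_oromanual", "right_oromanual", "both_oromanual")
  runs_to_epochs(oro, etho$time_s, etho$frame_rate)
}

#' Food-handling epochs per condition
#'
#' A frame belongs to a condition's food handling when the combined state is
#' that hand's holding or oromanual state (unimanual conditions) or a "both"
#' holding/oromanual state (bimanual). "both_other" frames belong to none.
#'
#' @param etho an ethogram.
#' @param hemisphere recorded hemisphere for hand -> condition resolution.
#' @return data.frame `start_s`, `end_s`, `condition`.
#' @export
condition_epochs <- function(etho, hemisphere) {
  cond_of <- c(
    left_holding = resolve_condition("left", hemisphere),
    left_oromanual = resolve_condition("left", hemisphere),
    right_holding = resolve_condition("right", hemisphere),
    right_oromanual = resolve_condition("right", hemisphere),
    both_holding = "bimanual", both_oromanual = "bimanual",
    both_other = NA_character_)
  lab <- unname(cond_of[etho$combined])
  out <- lapply(CONDITIONS, function(cc) {
    ep <- runs_to_epochs(!is.na(lab) & lab == cc, etho$time_s, etho$frame_rate)
    if (nrow(ep)) ep$condition <- cc
    ep
  })
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  if (!length(out))
    return(data.frame(start_s = numeric(), end_s = numeric(), condition = character()))
  do.call(rbind, out)
}

runs_to_epochs <- function(flag, time_s, frame_rate) {
  if (!any(flag)) return(data.frame(start_s = numeric(), end_s = numeric()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dt <- 1 / frame_rate
  data.frame(start_s = time_s[starts[keep]],
             end_s = time_s[ends[keep]] + dt)
}
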