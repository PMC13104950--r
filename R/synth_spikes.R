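#' Configuration for the synthetic population generator
#'
#' Units share low-rank, condition-dependent latent factors so that the
#' population's dimensionality and cross-condition geometry are controlled by
#' construction. The dependence mode fixes the relation between the
#' per-condition loading matrices:
#' * `invariant` — identical loadings in all three conditions;
#' * `laterality_dependent` — contralateral loadings rotated by `angle_deg`
#'   away from ipsilateral (default 90, orthogonal); bimanual is their
#'   normalized sum;
#' * `manuality_dependent` — both unimanual conditions share loadings;
#'   bimanual is rotated by `angle_deg`;
#' * `fully_dependent` — all three conditions pairwise orthogonal (at
#'   `angle_deg = 90`).
#'
#' @param n_units number of units.
#' @param baseline_mean_hz mean of the gamma-distributed per-unit baseline
#'   rates.
#' @param baseline_shape gamma shape of the baseline draw.
#' @param latent_dim latent dimensionality per condition.
#' @param mode dependence mode, see above.
#' @param angle_deg rotation between condition subspaces (degrees); `NULL`
#'   gives the mode's canonical value (0 for invariant, 90 otherwise).
#' @param profile `"transient"` (firing peaks around the transport, fl-M1
#'   like) or `"sustained"` (elevated throughout oromanual/ingestion, LOM
#'   like).
#' @param gain_hz typical per-unit rate modulation amplitude (Hz) at latent
#'   value 1.
#' @param noise_gain_hz amplitude (Hz, per-unit s.d.) of the smooth shared
#'   moment-to-moment fluctuations carried by the same condition loadings.
#'   These co-fluctuations are what give the population its condition-
#'   dependent pairwise correlation structure; 0 disables them.
#' @param noise_tau_s timescale (gaussian smoothing s.d.) of the shared
#'   fluctuations.
#' @param sustain_s duration of the sustained profile's plateau.
#' @param encoding `"latent_only"` or `"linear_kinematic"` (adds a lagged
#'   linear drive from the hand-nose distances to each unit's rate).
#' @param kin_gain_hz modulation amplitude of the kinematic drive per unit.
#' @param kin_lags_s lag grid (seconds, negative = past kinematics) for the
#'   kinematic taps.
#' @param bin_s discretization step for the rate -> Poisson conversion
#'   (1 ms; spikes are jittered uniformly within the bin).
#' @param area,hemisphere metadata attached to the generated recording.
#' @return list of class `population_config`.
#' @export
population_config <- function(n_units = 100, baseline_mean_hz = 8,
                              baseline_shape = 4, latent_dim = 2,
                              mode = c("invariant", "laterality_dependent",
                                       "manuality_dependent", "fully_dependent"),
                              angle_deg = NULL,
                              profile = c("transient", "sustained"),
                              gain_hz = 6, noise_gain_hz = 4, noise_tau_s = 0.15,
                              sustain_s = 1.2,
                              encoding = c("latent_only", "linear_kinematic"),
                              kin_gain_hz = 3,
                              kin_lags_s = seq(-0.1, 0, by = 0.005),
                              bin_s = 0.001,
                              area = "flM1", hemisphere = "left") {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  encoding <- match.arg(encoding)
  if (baseline_mean_hz < 0) stop("negative requested baseline")
  if (is.null(angle_deg)) angle_deg <- if (mode == "invariant") 0 else 90
  stopifnot(latent_dim >= 1, gain_hz >= 0, noise_gain_hz >= 0, bin_s > 0)
  if (n_units < 3L * latent_dim)
    stop("n_units must be at least 3 * latent_dim (orthogonal loadings need room)")
  structure(as.list(environment()), class = "population_config")
}

# latent temporal basis, evaluated on an offset grid (seconds from onset).
# transient: gaussian bump + biphasic derivative; sustained: smooth plateau
# over `sustain_s` + slow ramp. Peak magnitudes are ~1.
latent_basis <- function(profile, q, sustain_s) {
  if (profile == "transient") {
    support <- c(-0.3, 0.6)
    fns <- list(
      function(tau) exp(-(tau - 0.03)^2 / (2 * 0.06^2)),
      function(tau) {
        g <- -(tau - 0.08) / 0.08 * exp(-(tau - 0.08)^2 / (2 * 0.08^2))
        g / 0.6065307  # normalize peak to ~1
      })
  } else {
    support <- c(-0.3, sustain_s + 0.8)
    fns <- list(
      function(tau) stats::plogis(tau / 0.03) * stats::plogis((sustain_s - tau) / 0.15),
      function(tau) pmax(0, pmin(tau / sustain_s, 1)) *
        stats::plogis((sustain_s + 0.2 - tau) / 0.1))
  }
  if (q > length(fns)) {  # extra dims: shifted copies of the first basis
    for (k in seq(length(fns) + 1L, q))
      local({
        shift <- 0.12 * (k - 2L)
        fns[[k]] <<- function(tau) fns[[1L]](tau - shift)
      })
  }
  list(fns = fns[seq_len(q)], support = support)
}

# loadings per condition given mode/angle: columns of U are orthonormal
condition_loadings <- function(n_units, q, mode, angle_deg) {
  U <- qr.Q(qr(matrix(stats::rnorm(n_units * 3L * q), n_units, 3L * q)))
  U1 <- U[, seq_len(q), drop = FALSE]
  U2 <- U[, q + seq_len(q), drop = FALSE]
  U3 <- U[, 2L * q + seq_len(q), drop = FALSE]
  th <- angle_deg * pi / 180
  rot <- function(A, B) cos(th) * A + sin(th) * B
  W <- switch(mode,
    invariant = list(ipsilateral = U1, contralateral = U1, bimanual = U1),
    laterality_dependent = {
      Wc <- rot(U1, U2)
      Wb <- U1 + Wc
      Wb <- sweep(Wb, 2, sqrt(colSums(Wb^2)), "/")
      list(ipsilateral = U1, contralateral = Wc, bimanual = Wb)
    },
    manuality_dependent = list(ipsilateral = U1, contralateral = U1,
                               bimanual = rot(U1, U3)),
    fully_dependent = list(ipsilateral = U1, contralateral = rot(U1, U2),
                           bimanual = rot(U1, U3)))
  W
}

#' Generate inhomogeneous-Poisson spike trains driven by condition-dependent
#' latents
#'
#' Each unit's rate is `max(0, baseline + gain * loadings %*% latent(t))`,
#' optionally plus a lag-filtered linear drive from the hand-nose distances
#' (`encoding = "linear_kinematic"`). The latent time courses carry the
#' event-locked gain profile around every (non-excluded) transport event of
#' the corresponding condition. Rates are discretized at `bin_s` (1 ms),
#' counts drawn Poisson per bin, and spikes jittered uniformly within the
#' bin.
#'
#' @param kin kinematics data.frame (with derived distances) giving the time
#'   base; the recording duration is the last frame plus one frame step.
#' @param events data.frame of transport events with `onset_s` and
#'   `condition`; at least one condition must be covered.
#' @param config a [population_config()].
#' @param seed integer RNG seed.
#' @param epochs optional data.frame `start_s, end_s, condition` confining
#'   each condition's shared fluctuations to its food-handling epochs;
#'   without it, each condition's active window spans its events plus 3 s
#'   margins.
#' @return list: `recording` (a [recording()]), `truth` (loadings per
#'   condition, baselines, kinematic taps if any, config echo).
#' @export
generate_spikes <- function(kin, events, config, seed = 1L, epochs = NULL) {
  cfg <- config
  set.seed(seed)
  if (!nrow(events)) stop("events must cover at least one condition")
  fr <- attr(kin, "frame_rate") %||% (1 / stats::median(diff(kin$time_s)))
  duration <- max(kin$time_s) + 1 / fr
  bs <- cfg$bin_s
  nt <- floor(duration / bs)
  tgrid <- (seq_len(nt) - 0.5) * bs
  q <- cfg$latent_dim

  baseline <- stats::rgamma(cfg$n_units, shape = cfg$baseline_shape,
                            rate = cfg$baseline_shape / cfg$baseline_mean_hz)
  W <- condition_loadings(cfg$n_units, q, cfg$mode, cfg$angle_deg)
  bas <- latent_basis(cfg$profile, q, cfg$sustain_s)

  # latent time courses per condition: sum of profile copies at event onsets
  Z <- lapply(CONDITIONS, function(cc) {
    on <- events$onset_s[events$condition == cc]
    z <- matrix(0, nt, q)
    for (e in on) {
      idx <- which(tgrid >= e + bas$support[1] & tgrid <= e + bas$support[2])
      if (!length(idx)) next
      tau <- tgrid[idx] - e
      for (k in seq_len(q)) z[idx, k] <- z[idx, k] + bas$fns[[k]](tau)
    }
    z
  })
  names(Z) <- CONDITIONS

  # smooth shared fluctuations through the same loadings, confined to each
  # condition's active window: these create the condition-dependent pairwise
  # correlation structure
  Znoise <- NULL
  if (cfg$noise_gain_hz > 0) {
    Znoise <- lapply(CONDITIONS, function(cc) {
      on <- events$onset_s[events$condition == cc]
      if (!length(on)) return(NULL)
      if (!is.null(epochs) && cc %in% epochs$condition) {
        ep <- epochs[epochs$condition == cc, , drop = FALSE]
      } else {
        ep <- data.frame(start_s = min(on) - 3, end_s = max(on) + 3)
      }
      active <- rep(FALSE, nt)
      for (e in seq_len(nrow(ep)))
        active[tgrid >= ep$start_s[e] & tgrid < ep$end_s[e]] <- TRUE
      # generate at 100 Hz, gaussian-smooth, interpolate to the 1 ms grid
      coarse_t <- seq(0, duration, by = 0.01)
      half <- ceiling(3 * cfg$noise_tau_s / 0.01)
      kern <- stats::dnorm(-half:half, sd = cfg$noise_tau_s / 0.01)
      kern <- kern / sum(kern)
      z <- vapply(seq_len(q), function(k) {
        w <- stats::rnorm(length(coarse_t) + 2L * half)
        sm <- stats::filter(w, kern, sides = 2L)[half + seq_along(coarse_t)]
        sm <- sm / stats::sd(sm, na.rm = TRUE)
        stats::approx(coarse_t, sm, xout = tgrid, rule = 2)$y
      }, numeric(nt))
      z * active
    })
    names(Znoise) <- CONDITIONS
  }

  # optional lagged kinematic drive (standardized distances, NA -> 0)
  kin_drive <- NULL
  taps <- NULL
  if (cfg$encoding == "linear_kinematic") {
    feats <- cbind(kin$d_left_nose, kin$d_right_nose)
    feats <- scale(feats)
    feats[is.na(feats)] <- 0
    fidx <- pmin(pmax(floor(tgrid * fr) + 1L, 1L), nrow(feats))
    nlag <- length(cfg$kin_lags_s)
    taps <- array(stats::rnorm(cfg$n_units * nlag * 2L, 0, 1), c(cfg$n_units, nlag, 2L))
    # smooth taps over the lag axis so they look like filters
    for (u in seq_len(cfg$n_units)) for (f in 1:2)
      taps[u, , f] <- stats::filter(taps[u, , f], rep(1 / 3, 3), circular = TRUE)
    taps <- taps * cfg$kin_gain_hz / sqrt(nlag * 2L)
    lag_steps <- round(cfg$kin_lags_s * fr)
    kin_drive <- function(u) {
      out <- numeric(nt)
      for (j in seq_len(nlag)) {
        src <- pmin(pmax(fidx + lag_steps[j], 1L), nrow(feats))
        out <- out + feats[src, 1L] * taps[u, j, 1L] + feats[src, 2L] * taps[u, j, 2L]
      }
      out
    }
  }

  units <- vector("list", cfg$n_units)
  gain <- cfg$gain_hz * sqrt(cfg$n_units)  # unit-norm columns -> per-unit ~gain_hz
  ngain <- cfg$noise_gain_hz * sqrt(cfg$n_units)
  block_size <- max(1L, min(cfg$n_units, floor(4e6 / nt)))
  for (b0 in seq(1L, cfg$n_units, by = block_size)) {
    blk <- b0:min(cfg$n_units, b0 + block_size - 1L)
    R <- matrix(rep(baseline[blk], each = nt), nt)
    if (cfg$gain_hz > 0)
      for (cc in CONDITIONS)
        R <- R + gain * (Z[[cc]] %*% t(W[[cc]][blk, , drop = FALSE]))
    if (!is.null(Znoise))
      for (cc in CONDITIONS)
        if (!is.null(Znoise[[cc]]))
          R <- R + ngain * (Znoise[[cc]] %*% t(W[[cc]][blk, , drop = FALSE]))
    if (!is.null(kin_drive)) for (j in seq_along(blk))
      R[, j] <- R[, j] + kin_drive(blk[j])
    counts <- matrix(stats::rpois(length(R), pmax(0, R) * bs), nt)
    for (j in seq_along(blk)) {
      u <- blk[j]
      hit <- which(counts[, j] > 0L)
      st <- rep((hit - 1L) * bs, counts[hit, j]) +
        stats::runif(sum(counts[hit, j])) * bs
      st <- pmin(sort(st), duration)
      units[[u]] <- spike_train(sprintf("u%03d", u), st,
                                unit_class = sample(c("single", "multi"), 1L))
    }
  }
  rec <- recording(units, duration = duration, area = cfg$area,
                   hemisphere = cfg$hemisphere)
  list(recording = rec,
       truth = list(loadings = W, baseline_hz = baseline, taps = taps,
                    kin_lags_s = cfg$kin_lags_s, mode = cfg$mode,
                    profile = cfg$profile, config = cfg))
}

#' Canned synthetic scenarios
#'
#' Bundles a behavior session, a matched spiking population and all ground
#' truth, writable via [write_bundle()]:
#' * `flM1_like` — transient event-locked gain, laterality-dependent
#'   loadings (responses peak around the transport, differ across hands);
#' * `LOM_like` — sustained gain throughout oromanual/ingestion, invariant
#'   loadings (condition-independent population structure);
#' * `null` — no event-locked modulation at all (gain 0);
#' * `linear_decode` — homogeneous-Poisson population plus a kinematic
#'   target constructed as a known lag-filter applied to the binned spikes,
#'   with the true taps stored for recovery tests.
#'
#' @param name scenario name.
#' @param seed integer RNG seed.
#' @param n_units,cycles_per_condition size overrides (defaults per
#'   scenario).
#' @param snr signal-to-noise variance ratio of the `linear_decode` target
#'   (`Inf` = noiseless).
#' @return list with `name`, `recording`, `kinematics`, `events` (ground
#'   truth), `truth` (generator parameters incl. ethogram truth), and for
#'   `linear_decode` also `target` (the decodable trace, one value per 5 ms
#'   bin) and `epochs`.
#' @export
make_scenario <- function(name = c("flM1_like", "LOM_like", "null", "linear_decode"),
                          seed = 1L, n_units = NULL, cycles_per_condition = NULL,
                          snr = 10) {
  name <- match.arg(name)
  if (name == "linear_decode") {
    nu <- n_units %||% 12L
    dur <- 240
    bcfg <- behavior_config(cycles_per_condition = 2, schedule = "both",
                            duration_s = dur)
    beh <- generate_kinematics(bcfg, seed = seed)
    pcfg <- population_config(n_units = nu, baseline_mean_hz = 15, gain_hz = 0)
    sp <- generate_spikes(beh$kinematics, beh$events[beh$events$kind == "transport", ],
                          pcfg, seed = seed + 1L)
    bin <- 0.005
    counts <- bin_spikes(sp$recording, bin)          # nbins x units
    lags <- -40:10                                   # decoder tap convention
    set.seed(seed + 2L)
    taps <- matrix(0, nu, length(lags))
    for (u in seq_len(nu)) {
      ctr <- stats::runif(1, -30, 0)
      taps[u, ] <- stats::rnorm(1, 0, 1) * exp(-(lags - ctr)^2 / (2 * 6^2))
    }
    taps <- taps / sqrt(sum(taps^2)) * 2
    y <- lag_filter_apply(counts, taps, lags)
    sig_var <- stats::var(y, na.rm = TRUE)
    y_noisy <- if (is.finite(snr))
      y + stats::rnorm(length(y), 0, sqrt(sig_var / snr)) else y
    return(list(name = name, recording = sp$recording,
                kinematics = beh$kinematics,
                events = data.frame(onset_s = numeric(), hand = character(),
                                    condition = character(), kind = character()),
                target = y_noisy, target_noiseless = y,
                epochs = data.frame(start_s = 0, end_s = sp$recording$duration,
                                    condition = "bimanual"),
                truth = c(sp$truth, list(decode_taps = taps, decode_lags = lags,
                                         snr = snr, bin_s = bin))))
  }
  defaults <- switch(name,
    flM1_like = list(nu = 48L, cyc = 16L, mode = "laterality_dependent",
                     profile = "transient", gain = 6),
    LOM_like = list(nu = 48L, cyc = 16L, mode = "invariant",
                    profile = "sustained", gain = 6),
    null = list(nu = 20L, cyc = 8L, mode = "invariant",
                profile = "transient", gain = 0))
  nu <- n_units %||% defaults$nu
  cyc <- cycles_per_condition %||% defaults$cyc
  beh <- generate_kinematics(behavior_config(cycles_per_condition = cyc),
                             seed = seed)
  pcfg <- population_config(n_units = nu, mode = defaults$mode,
                            profile = defaults$profile, gain_hz = defaults$gain)
  sp <- generate_spikes(beh$kinematics,
                        beh$events[beh$events$kind == "transport", ],
                        pcfg, seed = seed + 1L)
  truth <- c(sp$truth, list(behavior = beh$truth))
  if (name == "null") truth$loadings <- NULL  # no modulation parameter stored
  list(name = name, recording = sp$recording, kinematics = beh$kinematics,
       events = beh$events, truth = truth)
}

# counts matrix (bins x units) over the whole recording at bin width `bin_s`
bin_spikes <- function(rec, bin_s) {
  nb <- floor(rec$duration / bin_s)
  edges <- seq(0, by = bin_s, length.out = nb + 1L)
  vapply(rec$units, function(u) {
    lo <- findInterval(edges[-length(edges)], u$spike_times, left.open = TRUE)
    hi <- findInterval(edges[-1L], u$spike_times, left.open = TRUE)
    as.numeric(hi - lo)
  }, numeric(nb))
}

# y[t] = sum_u sum_j taps[u,j] * counts[t + lags[j], u], NA near the edges
lag_filter_apply <- function(counts, taps, lags) {
  nb <- nrow(counts)
  y <- numeric(nb)
  for (j in seq_along(lags)) {
    src <- seq_len(nb) + lags[j]
    ok <- src >= 1L & src <= nb
    y[ok] <- y[ok] + as.vector(counts[src[ok], , drop = FALSE] %*% taps[, j])
    y[!ok] <- NA_real_
  }
  y
}

#' Write a scenario bundle as the CSV/JSON file set
#'
#' Emits `spikes.csv` + `spikes.json`, `kinematics.csv`, `events.csv` and
#' `ground_truth.json` under `dir`.
#'
#' @param bundle a [make_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spikes(bundle$recording, file.path(dir, "spikes.csv"))
  write_kinematics(bundle$kinematics, file.path(dir, "kinematics.csv"))
  write_events(bundle$events, file.path(dir, "events.csv"))
  gt <- bundle$truth
  gt$config <- NULL
  gt$behavior <- NULL  # per-frame truth stays in memory, too large for JSON
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
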