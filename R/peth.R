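#' Build a transport-aligned peri-event time histogram for one unit
#'
#' Aligns spike times to each event onset and bins them in 20 ms bins from
#' one second before to one second after the onset (100 bins). Bin edges are
#' half-open `[t, t + 20 ms)`: a spike exactly at onset falls in the first
#' post-onset bin. Bins that overlap an oromanual/ingestion epoch belonging
#' to a *different* cycle than the aligned event are masked per trial, as are
#' bins extending past the recording edges; masked bins are excluded from all
#' means, never zero-filled.
#'
#' @param unit a [spike_train()] (or bare numeric spike-time vector).
#' @param onsets event onset times (seconds) for one condition.
#' @param duration recording duration in seconds.
#' @param oro_epochs optional data.frame `start_s`,`end_s` of
#'   oromanual/ingestion epochs used for cross-cycle masking.
#' @param config configuration list (`config$peth`).
#' @return object of class `peth`: `counts` and `rate` (trials x bins; rate =
#'   count / bin width, `NA` where masked), `mask` (TRUE = valid),
#'   `bin_centers`, `onsets`, `n_trials`, bookkeeping flags.
#' @export
build_peth <- function(unit, onsets, duration, oro_epochs = NULL,
                       config = default_config()) {
  cfg <- config$peth
  st <- if (inherits(unit, "spike_train")) unit$spike_times else as.numeric(unit)
  bw <- cfg$bin_width_s
  edges_rel <- seq(cfg$window_s[1], cfg$window_s[2], by = bw)
  nb <- length(edges_rel) - 1L
  nev <- length(onsets)
  if (!nev) stop("build_peth needs at least one event")
  edges <- outer(onsets, edges_rel, "+")             # trials x (nb+1)
  lt <- matrix(findInterval(edges, st, left.open = TRUE), nev)
  counts <- lt[, -1L, drop = FALSE] - lt[, -(nb + 1L), drop = FALSE]
  mask <- edges[, -(nb + 1L), drop = FALSE] >= 0 &
    edges[, -1L, drop = FALSE] <= duration
  if (!is.null(oro_epochs) && nrow(oro_epochs)) {
    own <- own_epoch_index(onsets, oro_epochs)
    for (i in seq_len(nev)) {
      other <- oro_epochs[setdiff(seq_len(nrow(oro_epochs)), own[i]), , drop = FALSE]
      if (!nrow(other)) next
      a <- edges[i, -(nb + 1L)]; b <- edges[i, -1L]
      overl <- vapply(seq_len(nb), function(j)
        any(other$start_s < b[j] & other$end_s > a[j]), logical(1))
      mask[i, overl] <- FALSE
    }
  }
  rate <- counts / bw
  rate[!mask] <- NA_real_
  structure(list(counts = counts, rate = rate, mask = mask,
                 bin_centers = edges_rel[-(nb + 1L)] + bw / 2,
                 bin_width = bw, window = cfg$window_s, onsets = onsets,
                 n_trials = nev, baseline = NULL,
                 baseline_subtracted = FALSE, zscored = FALSE),
            class = "peth")
}

# the epoch an event initiates: start closest to the onset within +-0.5 s
own_epoch_index <- function(onsets, oro_epochs) {
  vapply(onsets, function(on) {
    d <- abs(oro_epochs$start_s - on)
    i <- which.min(d)
    if (length(i) && d[i] <= 0.5) i else NA_integer_
  }, integer(1))
}

#' Trial-mean PETH rate (Hz per bin), masked bins excluded
#' @param peth a [build_peth()] result.
#' @return numeric vector of length 100.
#' @export
peth_mean <- function(peth) colMeans(peth$rate, na.rm = TRUE)

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth: %d trials x %d bins (%.0f ms), %s>\n", x$n_trials,
              ncol(x$counts), x$bin_width * 1e3,
              if (x$baseline_subtracted) "baseline-subtracted" else "raw"))
  invisible(x)
}

# max of the per-draw trial-mean PETH rate over the stat window for a batch
# of event-time draws (rows of `onset_mat`). Shared by the real statistic and
# the sham bootstrap so masking is applied symmetrically.
peth_max_batch <- function(st, onset_mat, edges_rel, duration, oro_bounds, bw) {
  nd <- nrow(onset_mat); nev <- ncol(onset_mat); K <- length(edges_rel)
  stat <- numeric(nd)
  chunk <- max(1L, floor(4e6 / (nev * K)))
  for (s0 in seq(1L, nd, by = chunk)) {
    rows <- s0:min(nd, s0 + chunk - 1L)
    flat <- as.vector(onset_mat[rows, , drop = FALSE])   # draw varies fastest
    times <- outer(flat, edges_rel, "+")
    lt <- matrix(findInterval(times, st, left.open = TRUE), length(flat))
    cnt <- lt[, -1L, drop = FALSE] - lt[, -K, drop = FALSE]
    ok <- times[, -K, drop = FALSE] >= 0 & times[, -1L, drop = FALSE] <= duration
    if (!is.null(oro_bounds)) {
      inb <- matrix(findInterval(times, oro_bounds) %% 2L == 1L, length(flat))
      ok <- ok & !(inb[, -K, drop = FALSE] | inb[, -1L, drop = FALSE])
    }
    grp <- rep(seq_along(rows), nev)
    sc <- rowsum(cnt * ok, grp)
    vc <- rowsum(ok + 0L, grp)
    mr <- sc / (vc * bw)
    mr[vc == 0L] <- -Inf
    stat[rows] <- apply(mr, 1L, max)
  }
  stat[!is.finite(stat)] <- 0
  stat
}

#' Sham-event bootstrap significance of a unit's transport response
#'
#' Sham event times are drawn uniformly over `[1 s, duration - 1 s]` in equal
#' number to the real events, `n_boot` times. The statistic is the maximum of
#' the trial-mean PETH over the window from 500 ms before to 500 ms after
#' onset. The right-tailed p-value is the number of sham maxima strictly
#' greater than the real maximum, divided by `n_boot` (ties favor
#' significance; smallest attainable p is 0, reported as such). If
#' `oro_epochs` is given, cross-cycle masking is applied to real and sham
#' PETHs symmetrically.
#'
#' @inheritParams build_peth
#' @param n_boot number of sham draws (default 1000).
#' @param seed integer RNG seed.
#' @return list with `p`, `real_max`, `sham_max` (length `n_boot`).
#'   A unit with no spikes returns `p = 1` by convention.
#' @export
bootstrap_significance <- function(unit, onsets, duration, oro_epochs = NULL,
                                   n_boot = 1000L, seed = 1L,
                                   config = default_config()) {
  cfg <- config$peth
  st <- if (inherits(unit, "spike_train")) unit$spike_times else as.numeric(unit)
  if (!length(st))
    return(list(p = 1, real_max = 0, sham_max = rep(0, n_boot)))
  stopifnot(n_boot >= 1L, length(onsets) >= 1L)
  edges_rel <- seq(cfg$stat_window_s[1], cfg$stat_window_s[2], by = cfg$bin_width_s)
  bounds <- NULL
  if (!is.null(oro_epochs) && nrow(oro_epochs)) {
    # event-own epochs are not exempted for shams (shams own no epoch); for
    # the real statistic the own epoch is exempt, handled via build_peth-style
    # masking below
    bounds <- as.vector(t(as.matrix(oro_epochs[order(oro_epochs$start_s),
                                               c("start_s", "end_s")])))
  }
  # real statistic: mask other-cycle epochs only
  real_p <- build_peth(st, onsets, duration, oro_epochs = oro_epochs,
                       config = config)
  sel <- real_p$bin_centers >= cfg$stat_window_s[1] &
    real_p$bin_centers <= cfg$stat_window_s[2]
  rm_ <- peth_mean(real_p)[sel]
  real_max <- if (all(is.na(rm_))) 0 else max(rm_, na.rm = TRUE)
  set.seed(seed)
  sham <- matrix(stats::runif(n_boot * length(onsets), 1, duration - 1),
                 n_boot, length(onsets))
  sham_max <- peth_max_batch(st, sham, edges_rel, duration, bounds,
                             cfg$bin_width_s)
  list(p = mean(sham_max > real_max), real_max = real_max, sham_max = sham_max)
}

#' Per-trial baseline subtraction
#'
#' The baseline of each trial is the mean firing rate from 1 s to 200 ms
#' before that trial's onset, over bins not masked (cross-cycle
#' oromanual/ingestion epochs inside the baseline window were masked at build
#' time). The baseline is subtracted from every bin of that trial. Trials
#' with no unmasked baseline bins are dropped with a warning.
#'
#' @param peth a raw [build_peth()] result.
#' @param config configuration list.
#' @return a `peth` with `baseline_subtracted = TRUE`, per-trial `baseline`
#'   values, possibly fewer trials.
#' @export
baseline_subtract <- function(peth, config = default_config()) {
  cfg <- config$peth
  if (peth$baseline_subtracted) stop("already baseline-subtracted")
  bsel <- peth$bin_centers >= cfg$baseline_window_s[1] &
    peth$bin_centers <= cfg$baseline_window_s[2]
  base <- rowMeans(peth$rate[, bsel, drop = FALSE], na.rm = TRUE)
  drop <- is.nan(base)
  if (any(drop)) {
    warning(sprintf("dropping %d trial(s) with fully-masked baseline window",
                    sum(drop)))
    peth$counts <- peth$counts[!drop, , drop = FALSE]
    peth$rate <- peth$rate[!drop, , drop = FALSE]
    peth$mask <- peth$mask[!drop, , drop = FALSE]
    peth$onsets <- peth$onsets[!drop]
    peth$n_trials <- sum(!drop)
    base <- base[!drop]
  }
  peth$rate <- peth$rate - base
  peth$baseline <- base
  peth$baseline_subtracted <- TRUE
  peth
}

#' Z-score a baseline-subtracted PETH
#'
#' Divides the unit's rates by the standard deviation of its
#' baseline-subtracted trial-mean PETH over the full window (the dispersion
#' the published methods leave unspecified; see the vignette). An all-zero
#' PETH stays all-zero (guarded division); the result is invariant to scaling
#' the unit's rates.
#'
#' @param peth a baseline-subtracted `peth`.
#' @return the `peth` with scaled rates and `zscored = TRUE`.
#' @export
zscore_peth <- function(peth) {
  if (!peth$baseline_subtracted) stop("z-score a baseline-subtracted PETH")
  m <- colMeans(peth$rate, na.rm = TRUE)
  s <- stats::sd(m[!is.nan(m)])
  if (is.na(s) || s == 0) s <- 1
  peth$rate <- peth$rate / s
  peth$zscored <- TRUE
  peth
}

VENN_CATEGORIES <- c("none", "ipsi_only", "contra_only", "bi_only",
                     "ipsi_contra", "ipsi_bi", "contra_bi", "all")

#' Classify per-unit responsiveness across the three conditions
#'
#' From the significance flags of the three per-condition bootstrap tests,
#' assigns each unit one of eight categories (the Venn cells of
#' {ipsilateral, contralateral, bimanual} plus "none"). Units missing any
#' condition are excluded from the proportion table.
#'
#' @param flags logical matrix, units x conditions, with columns named by
#'   `c("ipsilateral","contralateral","bimanual")`; `NA` marks an untested
#'   condition.
#' @return list: `category` (per unit; `NA` where a condition is missing),
#'   `proportions` (named 8-way proportions over fully-tested units),
#'   `responder_proportions` (over responders only, "none" excluded).
#' @export
categorize_responsiveness <- function(flags) {
  flags <- as.matrix(flags)[, CONDITIONS, drop = FALSE]
  cat_of <- function(f) {
    if (anyNA(f)) return(NA_character_)
    key <- paste0(as.integer(f), collapse = "")
    switch(key, "000" = "none", "100" = "ipsi_only", "010" = "contra_only",
           "001" = "bi_only", "110" = "ipsi_contra", "101" = "ipsi_bi",
           "011" = "contra_bi", "111" = "all")
  }
  category <- apply(flags, 1L, cat_of)
  tested <- category[!is.na(category)]
  prop <- prop.table(table(factor(tested, levels = VENN_CATEGORIES)))
  resp <- tested[tested != "none"]
  rprop <- if (length(resp))
    prop.table(table(factor(resp, levels = VENN_CATEGORIES[-1L]))) else
      table(factor(character(), levels = VENN_CATEGORIES[-1L]))
  list(category = category,
       proportions = stats::setNames(as.numeric(prop), names(prop)),
       responder_proportions = stats::setNames(as.numeric(rprop), names(rprop)))
}
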