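#' Response magnitude of a unit in one condition
#'
#' The response is the area under the baseline-subtracted trial-mean PETH in
#' a 100 ms (5-bin) window centred on the time of maximum mean firing, with
#' the peak searched over -200 ms to +500 ms relative to onset. Windows
#' truncated by the PETH edge (or fully-masked bins) are flagged.
#'
#' @param peth a baseline-subtracted [build_peth()] result.
#' @param peak_bin optionally force the peak bin index (used when the same
#'   per-unit peak time must be reused across conditions).
#' @param config configuration list.
#' @return list: `A` (Hz*s), `peak_time_s`, `peak_bin`, `truncated`.
#' @export
response_magnitude <- function(peth, peak_bin = NULL, config = default_config()) {
  cfg <- config$preference
  if (!peth$baseline_subtracted) stop("response_magnitude needs baseline-subtracted PETH")
  m <- peth_mean(peth)
  ctr <- peth$bin_centers
  if (is.null(peak_bin)) {
    sel <- which(ctr >= cfg$peak_window_s[1] & ctr <= cfg$peak_window_s[2] & !is.nan(m))
    if (!length(sel)) return(list(A = NA_real_, peak_time_s = NA_real_,
                                  peak_bin = NA_integer_, truncated = TRUE))
    peak_bin <- sel[which.max(m[sel])]
  }
  half <- (cfg$response_bins - 1L) %/% 2L
  win <- max(1L, peak_bin - half):min(length(m), peak_bin + half)
  vals <- m[win]
  truncated <- length(win) < cfg$response_bins || any(is.nan(vals))
  A <- sum(vals[!is.nan(vals)]) * peth$bin_width
  list(A = A, peak_time_s = ctr[peak_bin], peak_bin = peak_bin,
       truncated = truncated)
}

#' Per-trial response magnitudes at a fixed peak window
#' @param peth baseline-subtracted `peth`.
#' @param peak_bin the unit's peak bin (from [response_magnitude()]).
#' @param config configuration list.
#' @return numeric vector, one Hz*s response per trial.
#' @export
trial_responses <- function(peth, peak_bin, config = default_config()) {
  cfg <- config$preference
  half <- (cfg$response_bins - 1L) %/% 2L
  win <- max(1L, peak_bin - half):min(ncol(peth$rate), peak_bin + half)
  rowSums(peth$rate[, win, drop = FALSE], na.rm = TRUE) * peth$bin_width
}

#' Preference index (A - B) / (A + B)
#'
#' Bounded in `[-1, 1]` when `A + B > 0`; undefined (returned as `NA`) when
#' `A + B <= 0`, which can happen for suppressed units after baseline
#' subtraction. Vectorized; antisymmetric in its arguments and invariant to
#' scaling both by the same positive constant.
#'
#' @param A,B response magnitudes in the two conditions being compared.
#' @return numeric preference index.
#' @export
preference_index <- function(A, B) {
  out <- (A - B) / (A + B)
  out[(A + B) <= 0] <- NA_real_
  out
}

#' Strong laterality/manuality preference of one unit
#'
#' Laterality: a Mann-Whitney U test on the per-trial responses ipsilateral
#' vs contralateral; a p-value below `alpha` (uncorrected) assigns the side
#' with the larger mean response. Manuality: bimanual vs the *preferred*
#' unimanual condition (the one with the larger response; ties broken toward
#' contralateral). The two axis labels index the 3 x 3 preference grid.
#'
#' @param ipsi,contra,bi numeric vectors of per-trial responses (>= 3 trials
#'   per compared side).
#' @param alpha significance level (default 0.05, uncorrected).
#' @return list: `laterality` in `c("ipsi","none","contra")`, `manuality` in
#'   `c("uni","none","bi")`, `cell` (1..9, column-major over
#'   laterality x manuality), and the two p-values.
#' @export
classify_strong_preference <- function(ipsi, contra, bi, alpha = 0.05) {
  if (min(length(ipsi), length(contra), length(bi)) < 3L)
    stop("need at least 3 trials per side")
  mw <- function(a, b) suppressWarnings(stats::wilcox.test(a, b)$p.value)
  p_lat <- mw(ipsi, contra)
  laterality <- if (!is.na(p_lat) && p_lat < alpha) {
    if (mean(ipsi) > mean(contra)) "ipsi" else "contra"
  } else "none"
  uni <- if (mean(contra) >= mean(ipsi)) contra else ipsi  # ties -> contra
  p_man <- mw(uni, bi)
  manuality <- if (!is.na(p_man) && p_man < alpha) {
    if (mean(bi) > mean(uni)) "bi" else "uni"
  } else "none"
  li <- match(laterality, c("ipsi", "none", "contra"))
  mi <- match(manuality, c("uni", "none", "bi"))
  list(laterality = laterality, manuality = manuality,
       cell = (mi - 1L) * 3L + li, p_laterality = p_lat, p_manuality = p_man)
}

#' Hierarchically averaged cumulative distributions of preference indices
#'
#' Empirical CDFs are computed per recording on a common grid, then averaged
#' over probes, days and mice (unweighted at each level).
#'
#' @param units data.frame with columns `mouse, day, probe, area, pi`
#'   (undefined PIs already removed).
#' @param grid evaluation grid (default 201 points on `[-1, 1]`).
#' @return data.frame `area, grid, value` (the mean CDF per area).
#' @export
average_pi_cdfs <- function(units, grid = seq(-1, 1, length.out = 201)) {
  dt <- data.table::as.data.table(units)
  cdfs <- dt[, {
    f <- stats::ecdf(pi)
    list(grid = grid, value = f(grid))
  }, by = c("mouse", "day", "probe", "area")]
  out <- lapply(split(cdfs, by = "area"), function(g)
    hierarchical_average(as.data.frame(g)[, c("mouse", "day", "probe", "grid", "value")],
                         "grand"))
  do.call(rbind, lapply(names(out), function(a)
    data.frame(area = a, out[[a]])))
}

#' Two-sample Kolmogorov-Smirnov distance between averaged CDFs
#' @param f,g CDF values on a common grid.
#' @return max |f - g|, in `[0, 1]`.
#' @export
ks_distance <- function(f, g) max(abs(f - g))

# hierarchical (probe -> day -> mouse -> grand) unweighted mean of the rows
# of X, vectorized over columns; equivalent to hierarchical_average applied
# per column with one row per recording
ha_matrix <- function(X, mouse, day) {
  g_day <- paste(mouse, day)          # collapse probes within (mouse, day)
  cnt <- table(g_day)                 # sorted by name, matches rowsum order
  X <- rowsum(X, g_day) / as.vector(cnt)
  mouse_of <- mouse[match(names(cnt), g_day)]
  cnt2 <- table(mouse_of)
  X <- rowsum(X, mouse_of) / as.vector(cnt2)
  colMeans(X)
}

#' Permutation test on the KS distance between two areas' PI distributions
#'
#' The observed statistic is the KS distance between the two areas'
#' hierarchically averaged PI CDFs. Under the null, area labels are
#' reassigned to units at random (`n_perm` times); the p-value is the
#' fraction of permuted statistics greater than or equal to the observed one
#' (no +1 smoothing, mirroring the sham-bootstrap counting convention).
#'
#' @param units data.frame `mouse, day, probe, area, pi`; exactly two area
#'   labels.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @param grid CDF evaluation grid.
#' @return list of class `distribution_comparison`: `statistic`
#'   (`"ks_distance"`), `observed`, `p`, `n_perm`.
#' @export
ks_permutation_test <- function(units, n_perm = 10000L, seed = 1L,
                                grid = seq(-1, 1, length.out = 201)) {
  areas <- sort(unique(units$area))
  if (length(areas) != 2L) stop("need exactly two areas")
  # per-unit CDF indicators, grouped per (recording x area) by rowsum: the
  # statistic is identical to average_pi_cdfs + ks_distance but ~100x faster
  # inside the permutation loop
  M <- outer(units$pi, grid, "<=") + 0
  rec <- interaction(units$mouse, units$day, units$probe, drop = TRUE)
  rec_meta <- units[!duplicated(rec), c("mouse", "day", "probe")]
  rec_meta <- rec_meta[order(unique(as.integer(rec))), , drop = FALSE]
  stat <- function(area_lab) {
    gid <- (as.integer(rec) - 1L) * 2L + match(area_lab, areas)
    S <- rowsum(M, gid)
    ng <- as.vector(table(gid))
    cdfs <- S / ng
    ids <- as.integer(rownames(S))
    ri <- (ids - 1L) %/% 2L + 1L
    ai <- (ids - 1L) %% 2L + 1L
    mean_cdf <- lapply(1:2, function(a) {
      sel <- which(ai == a)
      if (!length(sel)) return(rep(NA_real_, length(grid)))
      ha_matrix(cdfs[sel, , drop = FALSE],
                rec_meta$mouse[ri[sel]], rec_meta$day[ri[sel]])
    })
    ks_distance(mean_cdf[[1L]], mean_cdf[[2L]])
  }
  observed <- stat(units$area)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(units$area)),
                 numeric(1))
  structure(list(statistic = "ks_distance", observed = observed,
                 p = mean(perm >= observed), n_perm = n_perm),
            class = "distribution_comparison")
}

#' Per-recording 3 x 3 preference-category histograms, averaged per area
#' @param units data.frame `mouse, day, probe, area, cell` (cell in 1..9).
#' @return matrix areas x 9 of mean proportions.
#' @export
average_category_histograms <- function(units) {
  dt <- data.table::as.data.table(units)
  h <- dt[, {
    tab <- prop.table(table(factor(cell, levels = 1:9)))
    list(cell = 1:9, value = as.numeric(tab))
  }, by = c("mouse", "day", "probe", "area")]
  out <- lapply(split(h, by = "area"), function(g) {
    a <- hierarchical_average(as.data.frame(g)[, c("mouse", "day", "probe", "cell", "value")],
                              "grand")
    a$value[order(a$cell)]
  })
  do.call(rbind, out)
}

#' Permutation test on the EMD between two areas' preference-grid histograms
#'
#' Observed statistic: the earth mover's distance, under the 3 x 3 Euclidean
#' grid metric (adjacent cells at unity distance), between the two areas'
#' hierarchically averaged category histograms. Permutation reassigns area
#' labels to units, as in [ks_permutation_test()].
#'
#' @param units data.frame `mouse, day, probe, area, cell`.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return `distribution_comparison` list with `statistic = "emd"`.
#' @export
emd_permutation_test <- function(units, n_perm = 10000L, seed = 1L) {
  areas <- sort(unique(units$area))
  if (length(areas) != 2L) stop("need exactly two areas")
  ground <- emd_grid_metric()
  # one-hot category matrix; group histograms by rowsum per permutation
  # (identical statistic to average_category_histograms + emd, much faster)
  M <- matrix(0, nrow(units), 9L)
  M[cbind(seq_len(nrow(units)), units$cell)] <- 1
  rec <- interaction(units$mouse, units$day, units$probe, drop = TRUE)
  rec_meta <- units[!duplicated(rec), c("mouse", "day", "probe")]
  rec_meta <- rec_meta[order(unique(as.integer(rec))), , drop = FALSE]
  stat <- function(area_lab) {
    gid <- (as.integer(rec) - 1L) * 2L + match(area_lab, areas)
    S <- rowsum(M, gid)
    hist <- S / rowSums(S)
    ids <- as.integer(rownames(S))
    ri <- (ids - 1L) %/% 2L + 1L
    ai <- (ids - 1L) %% 2L + 1L
    h2 <- lapply(1:2, function(a) {
      sel <- which(ai == a)
      ha_matrix(hist[sel, , drop = FALSE],
                rec_meta$mouse[ri[sel]], rec_meta$day[ri[sel]])
    })
    emd(h2[[1L]], h2[[2L]], ground)
  }
  observed <- stat(units$area)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(units$area)),
                 numeric(1))
  structure(list(statistic = "emd", observed = observed,
                 p = mean(perm >= observed), n_perm = n_perm),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("<%s = %.4g, permutation p = %.4g (%d permutations)>\n",
              x$statistic, x$observed, x$p, x$n_perm))
  invisible(x)
}
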