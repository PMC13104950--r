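#' Ethogram + transport-event stage
#'
#' Segments the kinematics (auto thresholds unless given), detects
#' transport-to-mouth events, and derives the oromanual and per-condition
#' food-handling epochs.
#'
#' @param kin kinematics with derived distances.
#' @param hemisphere recorded hemisphere.
#' @param thresholds optional manual per-hand thresholds.
#' @param config configuration list.
#' @return list: `ethogram`, `transports` (all, incl. excluded with
#'   reasons), `events` (included only), `oro_epochs`, `epochs`
#'   (per-condition food handling).
#' @export
stage_events <- function(kin, hemisphere, thresholds = NULL,
                         config = default_config()) {
  etho <- segment_ethogram(kin, thresholds, config)
  tr <- detect_transports(etho, kin, hemisphere, config)
  list(ethogram = etho, transports = tr,
       events = tr[!tr$excluded, , drop = FALSE],
       oro_epochs = oromanual_epochs(etho),
       epochs = condition_epochs(etho, hemisphere))
}

#' PETH + bootstrap-significance stage
#'
#' Builds per unit x condition PETHs, runs the sham-event bootstrap, flags
#' significance at `config$peth$alpha`, and classifies responsiveness.
#'
#' @param rec a [recording()].
#' @param events included transport events (`onset_s`, `condition`).
#' @param oro_epochs oromanual epochs for cross-cycle masking (or NULL).
#' @param config configuration list.
#' @param n_boot bootstrap draws (default from config).
#' @param seed integer RNG seed.
#' @return list: `peths` (nested `[[unit]][[condition]]`, raw), `p_values`
#'   and `flags` (units x conditions), `responsiveness`, `inclusion` (the
#'   peth-profile decision).
#' @export
stage_peth <- function(rec, events, oro_epochs = NULL,
                       config = default_config(),
                       n_boot = config$peth$n_boot, seed = 1L) {
  conds <- intersect(CONDITIONS, unique(events$condition))
  uids <- names(rec$units)
  pv <- matrix(NA_real_, length(uids), 3L, dimnames = list(uids, CONDITIONS))
  peths <- stats::setNames(vector("list", length(uids)), uids)
  for (ui in seq_along(uids)) {
    u <- rec$units[[ui]]
    pl <- list()
    for (cc in conds) {
      on <- events$onset_s[events$condition == cc]
      pl[[cc]] <- build_peth(u, on, rec$duration, oro_epochs, config)
      pv[ui, cc] <- bootstrap_significance(u, on, rec$duration, oro_epochs,
                                           n_boot = n_boot,
                                           seed = seed + 7L * ui, config = config)$p
    }
    peths[[ui]] <- pl
  }
  flags <- pv < config$peth$alpha
  resp <- categorize_responsiveness(flags)
  n_responsive <- sum(apply(flags, 1L, function(f) isTRUE(any(f))))
  incl <- check_inclusion(rec, events, "peth", n_responsive = n_responsive,
                          config = config)
  list(peths = peths, p_values = pv, flags = flags, responsiveness = resp,
       inclusion = incl)
}

#' Preference stage: responses, preference indices, strong-preference grid
#'
#' Baseline-subtracts each PETH, measures per-condition responses at each
#' condition's own peak (config-switchable to a shared peak), computes
#' laterality and manuality preference indices, and classifies the strong
#' preference grid cell from the per-trial responses.
#'
#' @param peths nested raw PETH list from [stage_peth()].
#' @param flags optional logical units x conditions significance matrix from
#'   [stage_peth()]; when given, preference indices are reported only for
#'   units significantly responsive to at least one transport type (the
#'   published analyses restrict PI distributions to responsive units, whose
#'   responses are positive — suppressed units can push the raw formula
#'   outside [-1, 1]).
#' @param config configuration list.
#' @return data.frame, one row per unit: responses `A_*`, `pi_laterality`,
#'   `pi_manuality`, peak times, `cell`, axis labels, `responsive`.
#' @export
stage_prefs <- function(peths, flags = NULL, config = default_config()) {
  rows <- lapply(names(peths), function(uid) {
    pl <- peths[[uid]]
    if (!all(CONDITIONS %in% names(pl))) return(NULL)
    bs <- lapply(pl, function(p)
      suppressWarnings(baseline_subtract(p, config)))
    shared_peak <- NULL
    if (!config$preference$peak_per_condition) {
      pooled <- Reduce(`+`, lapply(bs, peth_mean)) / length(bs)
      ctr <- bs[[1L]]$bin_centers
      sel <- which(ctr >= config$preference$peak_window_s[1] &
                     ctr <= config$preference$peak_window_s[2])
      shared_peak <- sel[which.max(pooled[sel])]
    }
    rm_ <- lapply(bs, response_magnitude, peak_bin = shared_peak, config = config)
    tr <- lapply(CONDITIONS, function(cc)
      trial_responses(bs[[cc]], rm_[[cc]]$peak_bin, config))
    names(tr) <- CONDITIONS
    grid <- tryCatch(
      classify_strong_preference(tr$ipsilateral, tr$contralateral, tr$bimanual,
                                 config$preference$mw_alpha),
      error = function(e) list(laterality = NA, manuality = NA, cell = NA_integer_))
    A <- vapply(rm_, `[[`, numeric(1), "A")
    pref_uni <- if (A[["contralateral"]] >= A[["ipsilateral"]])
      "contralateral" else "ipsilateral"
    responsive <- is.null(flags) || isTRUE(any(flags[uid, ]))
    pi_lat <- if (responsive)
      preference_index(A[["ipsilateral"]], A[["contralateral"]]) else NA_real_
    pi_man <- if (responsive)
      preference_index(A[["bimanual"]], A[[pref_uni]]) else NA_real_
    data.frame(unit_id = uid,
               A_ipsi = A[["ipsilateral"]], A_contra = A[["contralateral"]],
               A_bi = A[["bimanual"]],
               pi_laterality = pi_lat,
               pi_manuality = pi_man,
               responsive = responsive,
               peak_ipsi_s = rm_$ipsilateral$peak_time_s,
               peak_contra_s = rm_$contralateral$peak_time_s,
               peak_bi_s = rm_$bimanual$peak_time_s,
               laterality = grid$laterality, manuality = grid$manuality,
               cell = grid$cell)
  })
  do.call(rbind, rows)
}

#' Build the nested per-unit, per-condition PETH list without significance
#' testing
#'
#' Convenience wrapper producing the same structure as
#' [stage_peth()]`$peths` when the bootstrap is not needed (e.g. geometry on
#' populations whose responsiveness is known by construction).
#'
#' @inheritParams stage_peth
#' @return nested list `[[unit]][[condition]]` of raw [build_peth()] objects.
#' @export
build_peth_set <- function(rec, events, oro_epochs = NULL,
                           config = default_config()) {
  conds <- intersect(CONDITIONS, unique(events$condition))
  lapply(rec$units, function(u) {
    pl <- lapply(conds, function(cc)
      build_peth(u, events$onset_s[events$condition == cc], rec$duration,
                 oro_epochs, config))
    stats::setNames(pl, conds)
  })
}

# trials x T x N array of (raw) PETH rates for one condition across units;
# masked bins are NA
trial_array <- function(peths, condition) {
  keep <- vapply(peths, function(pl) condition %in% names(pl), logical(1))
  pl <- lapply(peths[keep], `[[`, condition)
  nt <- pl[[1L]]$n_trials; nb <- ncol(pl[[1L]]$rate)
  arr <- array(NA_real_, c(nt, nb, length(pl)))
  for (u in seq_along(pl)) arr[, , u] <- pl[[u]]$rate
  arr
}

#' Population-geometry stage
#'
#' Soft-normalized PCA per condition on the trial-mean PETHs, participation
#' ratios, and for each condition pair the first principal angle, top-10
#' alignment index and the invariant/orthogonal bootstrap predictions. Time
#' bins masked in any condition are dropped for all (valid-bin
#' intersection).
#'
#' @param peths nested raw PETH list from [stage_peth()].
#' @param events included events (for the pca inclusion rule).
#' @param rec the recording (for the inclusion rule).
#' @param config configuration list.
#' @param n_boot bootstrap iterations (default from config).
#' @param seed integer RNG seed.
#' @param run_orthogonal also compute the orthogonal predictions (slower).
#' @return list: `inclusion`, `conditions`, per-condition `participation`
#'   and `explained_top`, `pairs` (per pair: observed angle/alignment +
#'   prediction summaries), `predictions` (full bootstrap draws).
#' @export
stage_geometry <- function(peths, events, rec, config = default_config(),
                           n_boot = config$geometry$n_boot, seed = 1L,
                           run_orthogonal = TRUE) {
  g <- config$geometry
  incl <- check_inclusion(rec, events, "pca", config = config)
  conds <- incl$conditions
  if (!incl$include || length(conds) < 2L)
    return(list(inclusion = incl, conditions = conds, pairs = NULL))
  arrs <- stats::setNames(lapply(conds, function(cc) trial_array(peths, cc)), conds)
  # valid-bin intersection across conditions
  ok_bins <- Reduce(`&`, lapply(arrs, function(a)
    apply(!is.na(a), 2L, all)))
  arrs <- lapply(arrs, function(a) a[, ok_bins, , drop = FALSE])
  Xs <- lapply(arrs, function(a) soft_normalize(apply(a, c(2L, 3L), mean), g$soft_norm_c))
  percond <- lapply(Xs, function(X) {
    C <- activity_covariance(X)
    p <- pca_decompose(X, g$center)
    list(participation = participation_ratio(C), explained_top = p$explained[1L])
  })
  pairs <- list(); preds <- list()
  cmb <- utils::combn(conds, 2L, simplify = FALSE)
  for (pr in cmb) {
    key <- paste(pr, collapse = ":")
    obs <- condition_pair_geometry(Xs[[pr[1L]]], Xs[[pr[2L]]],
                                   k = g$angle_k, d = g$n_top, center = g$center)
    inv <- bootstrap_invariant_prediction(arrs[[pr[1L]]], arrs[[pr[2L]]],
                                          n_boot = n_boot, seed = seed,
                                          k = g$angle_k, d = g$n_top,
                                          soft_c = g$soft_norm_c, center = g$center)
    ort <- NULL
    if (run_orthogonal && all(c("ipsilateral", "contralateral") %in% conds)) {
      mode <- if (setequal(pr, c("ipsilateral", "contralateral")))
        "laterality" else "manuality"
      if (mode == "laterality" || all(CONDITIONS %in% conds))
        ort <- bootstrap_orthogonal_prediction(
          arrs, mode = mode, pair = pr, n_boot = n_boot, seed = seed + 1L,
          k = g$angle_k, d = g$n_top, soft_c = g$soft_norm_c,
          center = g$center,
          opt_args = list(tol = g$opt_tol, max_iter = g$opt_max_iter,
                          restarts = 0L))
    }
    pairs[[key]] <- list(observed = obs[c("angle_deg", "alignment")],
                         invariant_median = vapply(inv, stats::median, numeric(1)),
                         orthogonal_median = if (!is.null(ort))
                           vapply(ort, stats::median, numeric(1)) else NULL)
    preds[[key]] <- list(invariant = inv, orthogonal = ort)
  }
  list(inclusion = incl, conditions = conds, per_condition = percond,
       pairs = pairs, predictions = preds)
}

#' Correlation-structure stage
#'
#' Rate-filters the recording (0.5 Hz rule), bins at 5 ms over the
#' per-condition food-handling epochs, and computes the pairwise correlation
#' matrices and their between-condition similarities.
#'
#' @param rec a [recording()].
#' @param epochs per-condition epochs (from [stage_events()]).
#' @param events included events (for the inclusion rule).
#' @param config configuration list.
#' @return list: `inclusion`, `binned`, `structures`, `similarity`
#'   (data.frame pair x rho).
#' @export
stage_corr <- function(rec, epochs, events, config = default_config()) {
  cd <- config$corr_decode
  recf <- apply_rate_filter(rec, cd$min_rate_hz)
  binned <- bin_and_slice(recf, epochs, cd$bin_width_s)
  bins <- vapply(binned, function(b) nrow(b$counts), integer(1))
  incl <- check_inclusion(recf, events, "corr_decode", binned_bins = bins,
                          config = config)
  structures <- lapply(binned, pairwise_correlation_matrix)
  conds <- names(structures)
  sim <- if (length(conds) >= 2L) {
    cmb <- utils::combn(conds, 2L, simplify = FALSE)
    data.frame(
      cond_a = vapply(cmb, `[`, character(1), 1L),
      cond_b = vapply(cmb, `[`, character(1), 2L),
      rho = vapply(cmb, function(pr)
        between_condition_similarity(structures[[pr[1L]]], structures[[pr[2L]]]),
        numeric(1)))
  } else NULL
  list(inclusion = incl, binned = binned, structures = structures,
       similarity = sim)
}

# kinematic target (one coordinate of one hand) sampled at bin start times
kin_target <- function(kin, bin_t, hand, coord = "x") {
  fr <- attr(kin, "frame_rate")
  idx <- pmin(pmax(floor(bin_t * fr) + 1L, 1L), nrow(kin))
  col <- paste0(substr(hand, 1L, 1L), coord)
  val <- kin[[col]][idx]
  valid <- kin[[paste0(substr(hand, 1L, 1L), "_valid")]][idx]
  val[!valid] <- NA_real_
  val
}

#' Decoding stage
#'
#' Fits within-condition ridge decoders of the active hand's position for
#' each condition (unimanual: that condition's hand; bimanual: both hands),
#' evaluates cross-validated R^2 on the held-out third, and computes
#' cross-body and uni-to-bimanual generalization with their bootstrap nulls.
#'
#' @param rec a [recording()].
#' @param kin kinematics with derived distances.
#' @param epochs per-condition food-handling epochs.
#' @param events included events.
#' @param hemisphere recorded hemisphere.
#' @param config configuration list.
#' @param coord decoded coordinate (`"x"`, `"y"` or `"z"`). Default `"z"`:
#'   the vertical axis is on a common scale for both hands, which cross-body
#'   generalization requires (the x axis mirrors between hands).
#' @param lambda_grid,n_folds,n_boot_null overrides for run-time scaling.
#' @param seed integer RNG seed.
#' @return list: `inclusion`, `r2` (within-condition R^2 per
#'   condition/limb), `generalization` (data.frame with `delta_pct` and null
#'   summaries).
#' @export
stage_decode <- function(rec, kin, epochs, events, hemisphere,
                         config = default_config(), coord = "z",
                         lambda_grid = config$corr_decode$lambda_grid,
                         n_folds = config$corr_decode$n_folds,
                         n_boot_null = 0L, seed = 1L, max_bins = NULL) {
  cd <- config$corr_decode
  recf <- apply_rate_filter(rec, cd$min_rate_hz)
  binned <- bin_and_slice(recf, epochs, cd$bin_width_s)
  if (!is.null(max_bins))  # run-time cap for smoke runs; inclusion uses full counts
    binned_capped <- lapply(binned, function(b) {
      keep <- seq_len(min(nrow(b$counts), max_bins))
      list(counts = b$counts[keep, , drop = FALSE],
           splices = b$splices[b$splices <= length(keep)],
           bin_t = b$bin_t[keep])
    })
  bins <- vapply(binned, function(b) nrow(b$counts), integer(1))
  incl <- check_inclusion(recf, events, "corr_decode", binned_bins = bins,
                          config = config)
  hand_of <- function(cond) if (cond == "ipsilateral") hemisphere else
    setdiff(HEMISPHERES, hemisphere)
  jobs <- list(
    list(cond = "ipsilateral", hand = hand_of("ipsilateral")),
    list(cond = "contralateral", hand = hand_of("contralateral")),
    list(cond = "bimanual", hand = hand_of("ipsilateral")),
    list(cond = "bimanual", hand = hand_of("contralateral")))
  models <- list(); r2 <- list(); sets <- list()
  use <- if (is.null(max_bins)) binned else binned_capped
  for (jb in jobs) {
    if (!jb$cond %in% names(use)) next
    des <- lagged_design(use[[jb$cond]], cd$bin_width_s,
                         cd$lag_before_s, cd$lag_after_s)
    y <- kin_target(kin, use[[jb$cond]]$bin_t[des$rows], jb$hand, coord)
    if (all(is.na(y))) next
    sp <- split_sets(nrow(des$X))
    key <- paste(jb$cond, jb$hand, sep = ":")
    m <- fit_decoder(des$X[sp$tuning, , drop = FALSE], y[sp$tuning],
                     des$X[sp$training, , drop = FALSE], y[sp$training],
                     lambda_grid, n_folds)
    models[[key]] <- m
    sets[[key]] <- list(X = des$X[sp$testing, , drop = FALSE],
                        y = y[sp$testing])
    r2[[key]] <- evaluate_decoder(m, sets[[key]]$X, sets[[key]]$y)
  }
  gen <- list()
  add_gen <- function(type, from_key, to_key) {
    if (is.null(models[[from_key]]) || is.null(models[[to_key]])) return()
    gv <- generalize(models[[from_key]], models[[to_key]],
                     sets[[to_key]]$X, sets[[to_key]]$y)
    nulls <- if (n_boot_null > 0L) {
      pf <- bootstrap_generalization_null(models[[to_key]], sets[[to_key]]$X,
                                          sets[[to_key]]$y, "perfect",
                                          n_boot_null, seed, cd$n_chunks)
      nn <- bootstrap_generalization_null(models[[to_key]], sets[[to_key]]$X,
                                          sets[[to_key]]$y, "none",
                                          n_boot_null, seed + 1L, cd$n_chunks)
      c(perfect_median = stats::median(pf, na.rm = TRUE),
        none_median = stats::median(nn, na.rm = TRUE))
    } else c(perfect_median = NA_real_, none_median = NA_real_)
    gen[[length(gen) + 1L]] <<- data.frame(
      type = type, from = from_key, to = to_key,
      r2_within = gv$r2_within, r2_cross = gv$r2_cross,
      delta_pct = gv$delta_pct, t(nulls))
  }
  h_i <- hand_of("ipsilateral"); h_c <- hand_of("contralateral")
  add_gen("cross_body", paste0("ipsilateral:", h_i), paste0("contralateral:", h_c))
  add_gen("cross_body", paste0("contralateral:", h_c), paste0("ipsilateral:", h_i))
  add_gen("uni_to_bimanual", paste0("ipsilateral:", h_i), paste0("bimanual:", h_i))
  add_gen("uni_to_bimanual", paste0("contralateral:", h_c), paste0("bimanual:", h_c))
  list(inclusion = incl, r2 = unlist(r2),
       generalization = if (length(gen)) do.call(rbind, gen) else NULL,
       lambda = vapply(models, `[[`, numeric(1), "lambda"))
}

#' Run the full pipeline on a scenario bundle
#'
#' simulate -> ethogram -> peth -> prefs -> geometry -> corr -> decode, with
#' every stage's inclusion decision collected. Bootstrap counts and the
#' lambda grid can be scaled down for smoke runs.
#'
#' @param bundle a [make_scenario()] result (or an equivalent list with
#'   `recording`, `kinematics`).
#' @param config configuration list.
#' @param seed integer RNG seed.
#' @param n_boot_peth,n_boot_geom,n_boot_null stage bootstrap counts.
#' @param lambda_grid,n_folds,decode_max_bins decoder scaling knobs.
#' @param run_orthogonal compute orthogonal geometry predictions.
#' @return list with each stage's results and `inclusion_report`.
#' @export
run_pipeline <- function(bundle, config = default_config(), seed = 1L,
                         n_boot_peth = config$peth$n_boot,
                         n_boot_geom = config$geometry$n_boot,
                         n_boot_null = 0L,
                         lambda_grid = config$corr_decode$lambda_grid,
                         n_folds = config$corr_decode$n_folds,
                         decode_max_bins = NULL,
                         run_orthogonal = TRUE) {
  rec <- bundle$recording
  kin <- bundle$kinematics
  ev_stage <- stage_events(kin, rec$hemisphere, config = config)
  events <- ev_stage$events
  peth_stage <- stage_peth(rec, events, ev_stage$oro_epochs, config,
                           n_boot = n_boot_peth, seed = seed)
  prefs <- stage_prefs(peth_stage$peths, peth_stage$flags, config)
  geom <- stage_geometry(peth_stage$peths, events, rec, config,
                         n_boot = n_boot_geom, seed = seed,
                         run_orthogonal = run_orthogonal)
  corr <- stage_corr(rec, ev_stage$epochs, events, config)
  dec <- stage_decode(rec, kin, ev_stage$epochs, events, rec$hemisphere,
                      config, lambda_grid = lambda_grid, n_folds = n_folds,
                      n_boot_null = n_boot_null, seed = seed,
                      max_bins = decode_max_bins)
  list(events = ev_stage, peth = peth_stage, prefs = prefs, geometry = geom,
       corr = corr, decode = dec,
       inclusion_report = list(peth = peth_stage$inclusion,
                               pca = geom$inclusion,
                               corr_decode = corr$inclusion))
}
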