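#' Read a spikes CSV plus its JSON metadata sidecar into a recording
#'
#' The spikes file is a UTF-8 CSV with header `unit_id,time_s`. Session
#' metadata (area, hemisphere, duration, unit classes, identifiers) lives in a
#' JSON sidecar; by default `<path without .csv>.json`.
#'
#' @param path path to `spikes.csv`.
#' @param meta_path path to the metadata JSON; default replaces the `.csv`
#'   suffix with `.json`.
#' @return a [recording()].
#' @details Unsorted spike times within a unit are sorted with a warning.
#'   A spike time beyond the metadata duration is an error, as is an unknown
#'   area label. Units listed in the metadata with no spikes are kept (empty
#'   spike trains are legal).
#' @export
read_spikes <- function(path, meta_path = sub("\\.csv$", ".json", path)) {
  tab <- data.table::fread(path, colClasses = list(character = "unit_id"))
  if (!all(c("unit_id", "time_s") %in% names(tab)))
    stop("spikes file must have columns unit_id,time_s")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("area", "hemisphere", "duration", "units")
  if (!all(need %in% names(meta)))
    stop("metadata must contain: ", paste(need, collapse = ", "))
  umeta <- meta$units  # data.frame: unit_id, unit_class, channel
  units <- lapply(seq_len(nrow(umeta)), function(i) {
    st <- tab$time_s[tab$unit_id == umeta$unit_id[i]]
    ch <- if ("channel" %in% names(umeta)) umeta$channel[i] else NA_integer_
    spike_train(as.character(umeta$unit_id[i]), st,
                unit_class = umeta$unit_class[i], channel = ch)
  })
  recording(units, duration = meta$duration, area = meta$area,
            hemisphere = meta$hemisphere,
            mouse_id = meta$mouse_id %||% "m1",
            day_id = meta$day_id %||% "d1",
            probe_id = meta$probe_id %||% "p1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest decimal string that round-trips the double exactly
fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write a recording to a spikes CSV plus JSON metadata sidecar
#'
#' Canonical ordering: units in metadata order, spike times ascending within
#' unit, so that write-read-write round-trips byte-identical.
#'
#' @param rec a [recording()].
#' @param path output CSV path; the sidecar goes to the matching `.json`.
#' @param meta_path override for the sidecar path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(rec, path, meta_path = sub("\\.csv$", ".json", path)) {
  tab <- data.table::rbindlist(lapply(rec$units, function(u)
    data.table::data.table(unit_id = rep(u$unit_id, length(u$spike_times)),
                           time_s = fmt_full(u$spike_times))))
  if (!nrow(tab)) tab <- data.table::data.table(unit_id = character(), time_s = numeric())
  data.table::fwrite(tab, path)
  meta <- list(
    mouse_id = rec$mouse_id, day_id = rec$day_id, probe_id = rec$probe_id,
    area = rec$area, hemisphere = rec$hemisphere, duration = rec$duration,
    units = data.frame(
      unit_id = vapply(rec$units, `[[`, character(1), "unit_id"),
      unit_class = vapply(rec$units, `[[`, character(1), "unit_class"),
      channel = vapply(rec$units, `[[`, integer(1), "channel"),
      row.names = NULL
    )
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a kinematics CSV
#'
#' Schema: `time_s, lx, ly, lz, rx, ry, rz, nx, ny, nz, l_valid, r_valid,
#' n_valid`. Occluded samples carry `FALSE` validity flags (positions may be
#' anything and are ignored); missingness is never a sentinel number.
#'
#' @param path CSV path.
#' @return a data.frame of class `kinematics` (see [compute_distances()]).
#' @export
read_kinematics <- function(path) {
  k <- as.data.frame(data.table::fread(path))
  need <- c("time_s", "lx", "ly", "lz", "rx", "ry", "rz", "nx", "ny", "nz",
            "l_valid", "r_valid", "n_valid")
  if (!all(need %in% names(k))) stop("kinematics file missing columns")
  for (v in c("l_valid", "r_valid", "n_valid")) k[[v]] <- as.logical(k[[v]])
  class(k) <- c("kinematics", "data.frame")
  k
}

#' @rdname read_kinematics
#' @param kin a kinematics data.frame.
#' @export
write_kinematics <- function(kin, path) {
  cols <- c("time_s", "lx", "ly", "lz", "rx", "ry", "rz", "nx", "ny", "nz",
            "l_valid", "r_valid", "n_valid")
  out <- as.data.frame(kin)[, cols]
  for (v in cols[1:10]) out[[v]] <- fmt_full(out[[v]])
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read / write an events CSV (`onset_s, condition, kind` plus extras)
#' @param path CSV path.
#' @return data.frame of events.
#' @export
read_events <- function(path) as.data.frame(data.table::fread(path))

#' @rdname read_events
#' @param events events data.frame.
#' @export
write_events <- function(events, path) {
  ev <- as.data.frame(events)
  for (v in names(ev)) if (is.double(ev[[v]])) ev[[v]] <- fmt_full(ev[[v]])
  data.table::fwrite(ev, path)
  invisible(path)
}

#' Drop units firing below a minimum all-time average rate
#'
#' Exclusion is strict: a unit is removed when `spikes / duration` is
#' *less than* `min_rate`, so a unit at exactly the threshold is kept.
#'
#' @param rec a [recording()].
#' @param min_rate minimum all-time average rate in Hz (default 0.5).
#' @return a new recording containing only the retained units (possibly zero
#'   of them); the input is untouched.
#' @export
apply_rate_filter <- function(rec, min_rate = 0.5) {
  stopifnot(min_rate >= 0)
  keep <- unit_rates(rec) >= min_rate
  out <- rec
  out$units <- rec$units[keep]
  out
}

#' Inclusion decision for a recording under one of the analysis profiles
#'
#' Profiles mirror the published inclusion rules:
#' * `peth`: at least 10 units and at least 5 transports-to-mouth of each
#'   handedness; optionally at least 5 significantly responsive units once
#'   the bootstrap test has run (pass `n_responsive`).
#' * `pca`: at least 40 units; conditions with fewer than 15 transports are
#'   dropped from aggregation (not the recording), and the recording is
#'   excluded only if no condition survives.
#' * `corr_decode`: at least 10 units and all three conditions with at least
#'   5 transports and at least 1000 five-ms bins.
#'
#' @param rec a [recording()] (already rate-filtered where applicable).
#' @param events data.frame with a `condition` column (included events only),
#'   or a named vector of per-condition event counts.
#' @param profile `"peth"`, `"pca"` or `"corr_decode"`.
#' @param binned_bins named vector of per-condition bin counts (required for
#'   `corr_decode`).
#' @param n_responsive number of significantly responsive units, if known.
#' @param config config list (thresholds read from `config$inclusion`).
#' @return list with `include` (logical), `reasons` (character vector of
#'   failed criteria, machine-readable), and for `pca` also `conditions`
#'   (the includable subset).
#' @export
check_inclusion <- function(rec, events, profile = c("peth", "pca", "corr_decode"),
                            binned_bins = NULL, n_responsive = NULL,
                            config = default_config()) {
  profile <- match.arg(profile)
  thr <- config$inclusion[[profile]]
  counts <- if (is.data.frame(events)) {
    tab <- table(factor(events$condition, levels = CONDITIONS))
    stats::setNames(as.integer(tab), CONDITIONS)
  } else {
    out <- stats::setNames(integer(3), CONDITIONS)
    out[names(events)] <- as.integer(events)
    out
  }
  reasons <- character()
  nu <- n_units(rec)
  if (nu < thr$min_units) reasons <- c(reasons, sprintf("units<%d", thr$min_units))
  if (profile == "pca") {
    ok_cond <- names(counts)[counts >= thr$min_events]
    if (!length(ok_cond))
      reasons <- c(reasons, sprintf("no condition with events>=%d", thr$min_events))
    return(list(include = length(reasons) == 0L, reasons = reasons,
                conditions = ok_cond))
  }
  low <- counts < thr$min_events
  if (any(low))
    reasons <- c(reasons, sprintf("events<%d:%s", thr$min_events,
                                  paste(names(counts)[low], collapse = ",")))
  if (profile == "peth" && !is.null(n_responsive) && n_responsive < thr$min_responsive)
    reasons <- c(reasons, sprintf("responsive<%d", thr$min_responsive))
  if (profile == "corr_decode") {
    if (is.null(binned_bins)) stop("corr_decode profile needs binned_bins")
    bb <- stats::setNames(rep(0L, 3L), CONDITIONS)
    bb[names(binned_bins)] <- as.integer(binned_bins)
    lowb <- bb < thr$min_bins
    if (any(lowb))
      reasons <- c(reasons, sprintf("bins<%d:%s", thr$min_bins,
                                    paste(names(bb)[lowb], collapse = ",")))
  }
  list(include = length(reasons) == 0L, reasons = reasons)
}

HIERARCHY <- c("unit", "probe", "day", "mouse", "grand")

#' Hierarchical (unweighted) averaging over the recording hierarchy
#'
#' Averages are taken strictly in the order trials, then units on the same
#' probe, then probes on the same day, then days of the same mouse, then
#' mice. Each step is an unweighted mean of the level below; cells missing at
#' any level are ignored at that level, never imputed or zero-filled. Any
#' columns beyond the hierarchy keys and `value` (e.g. `condition`, a bin
#' index) are carried as grouping keys at every level.
#'
#' @param values data.frame with some subset of the key columns
#'   `mouse, day, probe, unit` plus a numeric `value` column and optional
#'   extra grouping columns.
#' @param target_level one of `"probe"`, `"day"`, `"mouse"`, `"grand"`.
#' @return data.frame aggregated to the target level, with the consumed key
#'   columns removed.
#' @export
hierarchical_average <- function(values, target_level = "grand") {
  if (!target_level %in% HIERARCHY[-1])
    stop("target_level must be one of ", paste(HIERARCHY[-1], collapse = ", "))
  dt <- data.table::as.data.table(values)
  if (!"value" %in% names(dt)) stop("values needs a 'value' column")
  keys <- c(mouse = "mouse", day = "day", probe = "probe", unit = "unit")
  extra <- setdiff(names(dt), c(keys, "value"))
  # consume one key per step: unit -> probe -> day -> mouse -> grand
  steps <- list(probe = "unit", day = "probe", mouse = "day", grand = "mouse")
  target_idx <- match(target_level, names(steps))
  for (s in seq_len(target_idx)) {
    drop_key <- steps[[s]]
    if (!drop_key %in% names(dt)) next  # already at or above this level
    by_cols <- c(setdiff(intersect(keys, names(dt)), drop_key), extra)
    dt <- dt[!is.na(value),
             list(value = mean(value)),
             by = by_cols]
  }
  as.data.frame(dt)
}
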