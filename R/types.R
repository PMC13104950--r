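#' Spike train for a single unit
#'
#' @param unit_id character scalar identifying the unit within its recording.
#' @param spike_times numeric vector of spike times in seconds. Must be
#'   non-negative; unsorted input is sorted with a warning.
#' @param unit_class `"single"` or `"multi"`. Single units and multiunits are
#'   treated identically by all analyses; the class is metadata.
#' @param channel optional integer channel index.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, unit_class = "multi", channel = NA_integer_) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L)
  unit_class <- match.arg(unit_class, c("single", "multi"))
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times)) stop("spike_times must not contain NA")
  if (length(spike_times) && min(spike_times) < 0) stop("negative spike times")
  if (is.unsorted(spike_times)) {
    warning(sprintf("unsorted spike times for unit %s: sorting", unit_id))
    spike_times <- sort(spike_times)
  }
  structure(
    list(unit_id = unit_id, spike_times = spike_times,
         unit_class = unit_class, channel = as.integer(channel)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes, class %s>\n",
              x$unit_id, length(x$spike_times), x$unit_class))
  invisible(x)
}

AREAS <- c("flM1", "flM2", "LOM")
HEMISPHERES <- c("left", "right")

#' The three food-handling condition labels
#' @format character vector `c("ipsilateral", "contralateral", "bimanual")`.
#' @export
CONDITIONS <- c("ipsilateral", "contralateral", "bimanual")

#' One probe insertion: spike trains plus session metadata
#'
#' @param units list of [spike_train()] objects (at least one).
#' @param duration recording duration in seconds. Spike times beyond
#'   `duration` are an error; duration always comes from metadata, never from
#'   the last spike.
#' @param area one of `"flM1"`, `"flM2"`, `"LOM"` (assigned upstream from
#'   histology; here a label).
#' @param hemisphere `"left"` or `"right"`; determines how left/right-hand
#'   events map onto ipsilateral/contralateral conditions.
#' @param mouse_id,day_id,probe_id identifier strings.
#' @return An object of class `recording`.
#' @export
recording <- function(units, duration, area, hemisphere,
                      mouse_id = "m1", day_id = "d1", probe_id = "p1") {
  if (!length(units)) stop("a recording needs at least one unit")
  stopifnot(all(vapply(units, inherits, logical(1), "spike_train")))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a positive scalar (seconds)")
  if (!area %in% AREAS) stop("unknown area label: ", area)
  hemisphere <- match.arg(hemisphere, HEMISPHERES)
  for (u in units) {
    if (length(u$spike_times) && max(u$spike_times) > duration)
      stop(sprintf("unit %s has spike times beyond duration", u$unit_id))
  }
  names(units) <- vapply(units, `[[`, character(1), "unit_id")
  structure(
    list(mouse_id = mouse_id, day_id = day_id, probe_id = probe_id,
         area = area, hemisphere = hemisphere,
         duration = duration, units = units),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s/%s/%s: %s %s hemisphere, %d units, %.1f s>\n",
              x$mouse_id, x$day_id, x$probe_id, x$area, x$hemisphere,
              length(x$units), x$duration))
  invisible(x)
}

#' Number of units in a recording
#' @param rec a [recording()].
#' @return integer count.
#' @export
n_units <- function(rec) length(rec$units)

#' Mean firing rates of all units
#' @param rec a [recording()].
#' @return named numeric vector, spikes / duration, in Hz.
#' @export
unit_rates <- function(rec) {
  vapply(rec$units, function(u) length(u$spike_times) / rec$duration, numeric(1))
}

#' Resolve a hand label into a condition label
#'
#' A hand contralateral to the recorded hemisphere gives the contralateral
#' condition; the same-side hand gives ipsilateral; `"both"` is bimanual.
#' Resolution happens once, at event detection or load, and is never
#' recomputed downstream.
#'
#' @param hand `"left"`, `"right"` or `"both"` (vectorized).
#' @param hemisphere recorded hemisphere, `"left"` or `"right"`.
#' @return character vector over `c("ipsilateral","contralateral","bimanual")`.
#' @export
resolve_condition <- function(hand, hemisphere) {
  hemisphere <- match.arg(hemisphere, HEMISPHERES)
  if (!all(hand %in% c("left", "right", "both")))
    stop("hand must be 'left', 'right' or 'both'")
  ifelse(hand == "both", "bimanual",
         ifelse(hand == hemisphere, "ipsilateral", "contralateral"))
}
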