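#' Default analysis configuration
#'
#' Every numeric constant used by the analysis stages, with the published
#' methods' values as defaults. Stored/loaded as JSON so runs are fully
#' reproducible from a single small text file.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    peth = list(
      bin_width_s = 0.02,          # 20 ms bins
      window_s = c(-1, 1),         # one second either side of onset
      baseline_window_s = c(-1, -0.2),
      stat_window_s = c(-0.5, 0.5),
      n_boot = 1000L,
      alpha = 0.001
    ),
    preference = list(
      peak_window_s = c(-0.2, 0.5),
      response_bins = 5L,          # 100 ms = 5 bins around the peak
      mw_alpha = 0.05,
      n_perm = 10000L,
      peak_per_condition = TRUE    # see Open Questions in the vignette
    ),
    ethogram = list(
      min_run_frames = 10L,
      speed_threshold_mm_s = 40,
      speed_smooth_frames = 11L,
      onset_fraction = 0.05,       # departure from pre-asymptote defining onset
      synchrony_window_s = 0.2,    # bimanual: both hands transition within this
      fit_margin_s = 0.4
    ),
    geometry = list(
      soft_norm_c = 5,             # divide by max rate + 5
      n_top = 10L,                 # alignment index uses top 10 PCs
      angle_k = 1L,                # subspace dim for the first principal angle
      center = TRUE,
      n_boot = 1000L,
      opt_tol = 1e-8,
      opt_max_iter = 5000L,
      opt_restarts = 3L,
      n_perm = 10000L
    ),
    corr_decode = list(
      bin_width_s = 0.005,         # 5 ms bins
      min_rate_hz = 0.5,           # strict exclusion below this
      lag_before_s = 0.2,          # decoding window: 200 ms before ...
      lag_after_s = 0.05,          # ... to 50 ms after the decoded bin
      lambda_grid = 10^seq(-2, 4, length.out = 13),
      n_folds = 5L,
      n_chunks = 20L,              # generalization nulls split testing set in 20ths
      n_boot = 1000L,
      n_perm = 10000L
    ),
    inclusion = list(
      peth = list(min_units = 10L, min_events = 5L, min_responsive = 5L),
      pca = list(min_units = 40L, min_events = 15L),
      corr_decode = list(min_units = 10L, min_events = 5L, min_bins = 1000L)
    )
  )
}

#' Read a JSON configuration file, filling unset values with defaults
#' @param path path to a JSON file; may set any subset of the fields of
#'   [default_config()].
#' @return full config list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  modifyList(default_config(), user)
}

#' Write a configuration list as JSON
#' @param config a config list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
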