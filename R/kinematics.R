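#' Derive hand-nose and hand-hand distance variables from marker positions
#'
#' Computes, per frame, the 3D Euclidean distances used throughout the
#' pipeline: `d_left_nose`, `d_right_nose`, `d_both_nose` (mid-point of the
#' two third digits to the nose) and `d_hand_hand` (D3 to D3). Distances
#' involving an invalid (occluded) marker are `NA`; `d_both_nose` is missing
#' wherever either hand or the nose is missing.
#'
#' @param kin data.frame with the kinematics schema of [read_kinematics()]
#'   (positions in mm on a uniform time grid, plus validity flags).
#' @return the input with the four derived distance columns added, classed
#'   `kinematics`. The frame rate is stored as attribute `frame_rate`.
#' @export
compute_distances <- function(kin) {
  kin <- as.data.frame(kin)
  dt <- diff(kin$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-12)
    stop("kinematics must be on a uniform time grid")
  l <- as.matrix(kin[, c("lx", "ly", "lz")])
  r <- as.matrix(kin[, c("rx", "ry", "rz")])
  n <- as.matrix(kin[, c("nx", "ny", "nz")])
  l[!kin$l_valid, ] <- NA_real_
  r[!kin$r_valid, ] <- NA_real_
  n[!kin$n_valid, ] <- NA_real_
  d3 <- function(a, b) sqrt(rowSums((a - b)^2))
  kin$d_left_nose  <- d3(l, n)
  kin$d_right_nose <- d3(r, n)
  kin$d_both_nose  <- d3((l + r) / 2, n)
  kin$d_hand_hand  <- d3(l, r)
  attr(kin, "frame_rate") <- if (length(dt)) 1 / stats::median(dt) else NA_real_
  class(kin) <- c("kinematics", "data.frame")
  kin
}
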