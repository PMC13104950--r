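#' Bin spikes into 5 ms counts and slice them into per-condition epochs
#'
#' Spike trains are binned at `bin_s` (bin phase anchored at each epoch's
#' start; partial terminal bins dropped) and the bins belonging to each
#' condition's food-handling epochs are concatenated in temporal order.
#' Epoch boundaries are recorded so lagged operations never span a splice.
#'
#' @param rec a (rate-filtered) [recording()].
#' @param epochs data.frame `start_s, end_s, condition` (e.g. from
#'   [condition_epochs()]).
#' @param bin_s bin width in seconds (default 0.005).
#' @return list of class `binned_epochs`, one entry per condition present:
#'   `counts` (bins x units), `splices` (row indices starting a new epoch),
#'   `bin_t` (bin start times), plus `bin_s` and unit ids as attributes.
#' @export
bin_and_slice <- function(rec, epochs, bin_s = 0.005) {
  sts <- lapply(rec$units, `[[`, "spike_times")
  out <- list()
  for (cc in intersect(CONDITIONS, unique(epochs$condition))) {
    ep <- epochs[epochs$condition == cc, , drop = FALSE]
    ep <- ep[order(ep$start_s), , drop = FALSE]
    nb_ep <- pmax(0L, floor((ep$end_s - ep$start_s) / bin_s))
    keep <- nb_ep >= 1L
    ep <- ep[keep, , drop = FALSE]; nb_ep <- nb_ep[keep]
    if (!nrow(ep)) next
    # one findInterval per unit over all epochs' bin starts at once
    starts <- unlist(lapply(seq_len(nrow(ep)), function(e)
      ep$start_s[e] + bin_s * (seq_len(nb_ep[e]) - 1L)))
    ends <- starts + bin_s
    cnt <- vapply(sts, function(st) {
      lo <- findInterval(starts, st, left.open = TRUE)
      hi <- findInterval(ends, st, left.open = TRUE)
      as.numeric(hi - lo)
    }, numeric(length(starts)))
    out[[cc]] <- list(counts = matrix(cnt, nrow = length(starts)),
                      splices = cumsum(c(1L, nb_ep[-length(nb_ep)])),
                      bin_t = starts)
  }
  attr(out, "bin_s") <- bin_s
  attr(out, "unit_ids") <- names(rec$units)
  class(out) <- "binned_epochs"
  out
}

#' Pairwise Pearson correlation matrix of one condition's binned activity
#'
#' Pearson's product-moment correlation between all units' concatenated
#' firing vectors. Pairs involving a zero-variance vector are flagged
#' undefined (`NA`) and excluded from the vectorized structure with a logged
#' count.
#'
#' @param binned one condition's entry of [bin_and_slice()] (list with
#'   `counts`), or a bare bins x units matrix.
#' @return list: `matrix` (N x N, unit diagonal, `NA` for undefined pairs),
#'   `vector` (strict upper triangle, undefined pairs removed),
#'   `pair_index` (upper-triangle indices kept), `n_undefined`.
#' @export
pairwise_correlation_matrix <- function(binned) {
  counts <- if (is.list(binned)) binned$counts else binned
  stopifnot(ncol(counts) >= 2L)
  v <- apply(counts, 2L, stats::var)
  R <- suppressWarnings(stats::cor(counts))
  R[v == 0, ] <- NA_real_
  R[, v == 0] <- NA_real_
  diag(R) <- 1
  ut <- upper.tri(R)
  vec <- R[ut]
  keep <- !is.na(vec)
  list(matrix = R, vector = vec[keep], pair_index = which(ut)[keep],
       n_undefined = sum(!keep))
}

#' Between-condition similarity of population correlation structure
#'
#' Pearson correlation between the vectorized upper triangles of two
#' conditions' correlation matrices. Pairs undefined in either condition are
#' dropped from both (identical unit sets are required).
#'
#' @param cs_A,cs_B results of [pairwise_correlation_matrix()] for the two
#'   conditions (same units, same order).
#' @return the similarity rho, in `[-1, 1]`.
#' @export
between_condition_similarity <- function(cs_A, cs_B) {
  stopifnot(nrow(cs_A$matrix) == nrow(cs_B$matrix))
  common <- intersect(cs_A$pair_index, cs_B$pair_index)
  if (length(common) < 3L) return(NA_real_)
  a <- cs_A$matrix[common]
  b <- cs_B$matrix[common]
  stats::cor(a, b)
}
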