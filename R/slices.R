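#' Trim low-coverage end slices of a lung mask
#'
#' Removes axial slices from the bottom inward and from the top inward while
#' their within-mask voxel count is below `min_voxels`. Interior slices below
#' the threshold are retained: trimming is contiguous from the ends only.
#'
#' @param counts integer vector of within-mask voxel counts per axial slice,
#'   ordered bottom to top.
#' @param min_voxels minimum count for an end slice to be retained
#'   (default 1000, the clinical-scale threshold; synthetic desk-scale
#'   configs use a smaller value in proportion to their slice size).
#' @return integer vector of retained slice indices (1-based, increasing).
#'   Fails with a subject-level error if no slice meets the threshold.
#' @examples
#' trim_slices(c(500, 1200, 900, 1500, 800), min_voxels = 1000) # 2 3 4
#' @export
trim_slices <- function(counts, min_voxels = 1000) {
  n <- length(counts)
  lo <- 1L
  while (lo <= n && counts[lo] < min_voxels) lo <- lo + 1L
  hi <- n
  while (hi >= 1L && counts[hi] < min_voxels) hi <- hi - 1L
  if (lo > hi) {
    insufficient_data(sprintf("no slice with >= %d masked voxels", min_voxels))
  }
  seq.int(lo, hi)
}

#' Select the nine decile slices of a trimmed lung
#'
#' Picks the 9 axial slices that split the retained slice stack into 10
#' equal-height segments: decile k (k = 1..9) is the retained slice at
#' position `round(k * n / 10)` (1-based, round-half-up), so decile 1 is
#' lowest and decile 9 uppermost.
#'
#' @param retained integer vector of retained slice indices (increasing), of
#'   length `n >= 10`.
#' @return integer vector of 9 strictly increasing slice indices.
#' @examples
#' select_decile_slices(1:20) # 2 4 6 8 10 12 14 16 18
#' @export
select_decile_slices <- function(retained) {
  n <- length(retained)
  if (n < 10) {
    insufficient_data(sprintf("only %d retained slices; need >= 10", n))
  }
  pos <- round_half_up(seq_len(9) * n / 10)
  retained[pos]
}
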