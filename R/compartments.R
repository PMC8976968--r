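# Compartment segmentation and area enumeration. Intervals are maximal runs
# of constant signal sign; every on-diagonal square and upper-triangle pair
# of intervals is a candidate area of one of the five pentad types.

AREA_TYPES <- c("A_short", "B_short", "A_long", "B_long", "AB")

#' Segment a compartment signal into A/B intervals
#'
#' Maximal runs of consecutive bins with constant sign become intervals
#' (positive = A, negative = B). Missing bins and bins with value exactly 0
#' terminate runs and belong to no interval.
#'
#' @param track A [binned_track()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open
#'   bin indices), `label` (`"A"`/`"B"`), `mean_signal`.
#' @export
segment_signal <- function(track) {
  if (!inherits(track, "BinnedTrack")) stop_validation("not a BinnedTrack")
  v <- track$values
  s <- sign(v)
  s[!is.finite(v) | s == 0] <- 0  # 0 = no call, breaks runs
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  if (!any(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      mean_signal = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(
    chrom = track$chrom,
    start = starts[keep], end = ends[keep],
    label = ifelse(r$values[keep] > 0, "A", "B"),
    mean_signal = vapply(which(keep), function(k)
      mean(v[(starts[k] + 1L):ends[k]]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# classify a label pair into a pentad type
.pair_type <- function(short, lab1, lab2) {
  ifelse(short, paste0(lab1, "_short"),
         ifelse(lab1 == lab2, paste0(lab1, "_long"), "AB"))
}

#' Enumerate candidate compartment areas in cis
#'
#' Emits every on-diagonal square (`A_short`/`B_short`) and every ordered
#' upper-triangle pair of intervals (`A_long`/`B_long`/`AB`): `n + n(n-1)/2`
#' areas for `n` intervals.
#'
#' @param intervals Output of [segment_signal()] for one chromosome.
#' @param binsize Bin size in bp (for the anchor distance annotation).
#' @return data.frame of area descriptors: interval bounds for rows and
#'   columns, `type`, midpoint-to-midpoint `distance` in bp (0 for
#'   short-range), `context = "cis"`.
#' @export
enumerate_areas_cis <- function(intervals, binsize) {
  n <- nrow(intervals)
  empty <- data.frame(chrom1 = character(), chrom2 = character(),
                      row_start = integer(), row_end = integer(),
                      col_start = integer(), col_end = integer(),
                      type = character(), distance = numeric(),
                      context = character(), stringsAsFactors = FALSE)
  if (!n) return(empty)
  if (is.unsorted(intervals$start))
    stop_validation("intervals must be sorted by start")
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  out <- data.frame(
    chrom1 = intervals$chrom[i], chrom2 = intervals$chrom[j],
    row_start = intervals$start[i], row_end = intervals$end[i],
    col_start = intervals$start[j], col_end = intervals$end[j],
    type = .pair_type(i == j, intervals$label[i], intervals$label[j]),
    distance = NA_real_, context = "cis", stringsAsFactors = FALSE)
  out$distance <- anchor_distance(out, binsize)
  out[order(i, j), , drop = FALSE]
}

#' Enumerate candidate compartment areas in trans
#'
#' Full cross product of the interval sets of two distinct chromosomes.
#' Types collapse to `A_long` (A x A), `B_long` (B x B) and `AB` (mixed);
#' anchor distance is undefined in trans.
#'
#' @param intervals_row,intervals_col [segment_signal()] outputs for the two
#'   chromosomes.
#' @return data.frame of area descriptors with `context = "trans"`.
#' @export
enumerate_areas_trans <- function(intervals_row, intervals_col) {
  if (nrow(intervals_row) && nrow(intervals_col) &&
      intervals_row$chrom[1] == intervals_col$chrom[1])
    stop_validation("trans enumeration requires two distinct chromosomes")
  n1 <- nrow(intervals_row); n2 <- nrow(intervals_col)
  if (!n1 || !n2)
    return(enumerate_areas_cis(intervals_row[0, ], 1)[0, ])
  g <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  data.frame(
    chrom1 = intervals_row$chrom[g$i], chrom2 = intervals_col$chrom[g$j],
    row_start = intervals_row$start[g$i], row_end = intervals_row$end[g$i],
    col_start = intervals_col$start[g$j], col_end = intervals_col$end[g$j],
    type = .pair_type(rep(FALSE, nrow(g)), intervals_row$label[g$i],
                      intervals_col$label[g$j]),
    distance = NA_real_, context = "trans", stringsAsFactors = FALSE)
}

#' Anchor distance of cis areas
#'
#' Midpoint-to-midpoint separation of the two intervals, in bp; 0 for
#' short-range (on-diagonal) areas. Midpoints sit at `(start + end)/2 *
#' binsize`.
#'
#' @param areas data.frame of cis area descriptors.
#' @param binsize Bin size in bp.
#' @return Numeric vector of distances in bp.
#' @export
anchor_distance <- function(areas, binsize) {
  if (any(areas$context != "cis"))
    stop_validation("anchor distance is undefined for trans areas")
  mid_r <- (areas$row_start + areas$row_end) / 2
  mid_c <- (areas$col_start + areas$col_end) / 2
  short <- areas$row_start == areas$col_start & areas$row_end == areas$col_end
  ifelse(short, 0, abs(mid_c - mid_r) * binsize)
}

#' Assign areas to genomic-distance strata
#'
#' Stratum `k` covers anchor distances in `[boundaries[k], boundaries[k+1])`.
#' Distances outside all strata (including the 0 of short-range areas unless
#' 0 falls inside a stratum) map to `NA`.
#'
#' @param distance Numeric vector of anchor distances in bp.
#' @param boundaries Strictly increasing numeric vector (>= 2 values) of
#'   stratum boundaries in bp.
#' @return Integer vector of 1-based stratum indices, `NA` for "none".
#' @export
assign_stratum <- function(distance, boundaries) {
  if (length(boundaries) < 2L || is.unsorted(boundaries, strictly = TRUE))
    stop_validation("'boundaries' must be >= 2 strictly increasing values")
  k <- findInterval(distance, boundaries)
  none <- is.na(k) | k < 1L | k >= length(boundaries)
  k[none] <- NA_integer_
  as.integer(k)
}
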