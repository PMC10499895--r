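#' Define a labelled region
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param label region label.
#' @return a one-row data.frame.
#' @export
region <- function(start, end, label = sprintf("%d-%d", start, end)) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid region: start must be <= end", call. = FALSE)
  data.frame(start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

#' Default PBX1 intron 2 breakpoint cluster regions
#'
#' Operational bounds for the two PBX1 breakpoint clusters (intron-end
#' cluster ~220-229 kb and mid-intron cluster ~120-155 kb). The published
#' description gives only approximate bounds; these defaults reproduce all
#' printed membership counts and are configuration values, not constants of
#' the method.
#'
#' @return data.frame of two regions.
#' @export
pbx1_cluster_regions <- function() {
  rbind(region(220000L, 229182L, "cluster1"),
        region(119000L, 155100L, "cluster2"))
}

#' Maximum-coverage sliding window
#'
#' Finds a window of fixed width containing the largest number of positions.
#' Only windows whose left edge coincides with an observed position need to
#' be considered (any optimal window can be shifted right until its left
#' edge hits a member without losing members); ties are broken by the
#' smallest such window start.
#'
#' @param positions integer vector of 1-based coordinates.
#' @param width window width in bp (window spans `start .. start+width-1`).
#' @param ids optional identifiers parallel to `positions`.
#' @return list with `window_start`, `width`, `count`, `members` (indices
#'   into `positions`) and `member_ids`.
#' @examples
#' max_coverage_window(c(1, 2, 3, 50), 10)$count  # 3
#' @export
max_coverage_window <- function(positions, width, ids = NULL) {
  if (length(positions) == 0L) stop("positions must be non-empty", call. = FALSE)
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be >= 1", call. = FALSE)
  positions <- as.integer(positions)
  starts <- sort(unique(positions))
  counts <- vapply(starts, function(s)
    sum(positions >= s & positions <= s + width - 1L), integer(1))
  best <- starts[which.max(counts)]  # which.max -> first (smallest) start
  members <- which(positions >= best & positions <= best + width - 1L)
  list(window_start = best, width = width, count = length(members),
       members = members,
       member_ids = if (!is.null(ids)) ids[members] else members)
}

#' Count breakpoints in fixed regions
#'
#' Assigns each break to the first region containing it (regions must be
#' non-overlapping; membership is inclusive of endpoints) or to `outside`,
#' optionally split by orientation.
#'
#' @param breaks data.frame with a `position` column and optionally an
#'   `orientation` column, or a bare integer vector of positions.
#' @param regions data.frame of regions as from [region()]/[rbind()].
#' @return data.frame with one row per region plus an `outside` row, with
#'   total and per-orientation counts.
#' @export
count_in_regions <- function(breaks, regions) {
  if (is.atomic(breaks)) breaks <- data.frame(position = as.integer(breaks))
  stopifnot(is.data.frame(regions), all(c("start", "end") %in% names(regions)))
  if (nrow(regions) > 1L) {
    o <- order(regions$start)
    if (any(regions$start[o][-1L] <= regions$end[o][-nrow(regions)]))
      stop("regions overlap", call. = FALSE)
  }
  pos <- breaks$position
  orient <- breaks$orientation %||% rep(NA_character_, length(pos))
  assign_to <- rep("outside", length(pos))
  for (i in seq_len(nrow(regions)))
    assign_to[pos >= regions$start[i] & pos <= regions$end[i]] <-
      regions$label[i]
  labels <- c(regions$label, "outside")
  out <- data.frame(
    label = labels,
    start = c(regions$start, NA), end = c(regions$end, NA),
    n = vapply(labels, function(l) sum(assign_to == l), integer(1)),
    stringsAsFactors = FALSE)
  if (!all(is.na(orient))) {
    for (lv in sort(unique(orient)))
      out[[lv]] <- vapply(labels, function(l)
        sum(assign_to == l & orient == lv), integer(1))
  }
  rownames(out) <- NULL
  out
}

#' Percentage with half-away-from-zero rounding
#'
#' @param count,total non-negative integers, `count <= total`, `total > 0`.
#' @param decimals decimal places in the result.
#' @return `100 * count / total` rounded half away from zero.
#' @examples
#' percent(57, 65)      # 88
#' percent(5, 65, 1)    # 7.7
#' @export
percent <- function(count, total, decimals = 0) {
  if (any(total <= 0)) stop("total must be > 0", call. = FALSE)
  if (any(count < 0 | count > total))
    stop("count must be in 0..total", call. = FALSE)
  round_half_away(100 * count / total, decimals)
}

#' Gap-based clustering of positions
#'
#' Groups sorted positions into clusters wherever consecutive spacing is at
#' most `max_gap`; an exploratory alternative to fixed region bounds.
#'
#' @param positions integer vector (empty input yields an empty result).
#' @param max_gap maximum within-cluster spacing in bp (`>= 0`).
#' @return data.frame with `start`, `end`, `count`, ordered by `start`.
#' @export
max_gap_clusters <- function(positions, max_gap) {
  max_gap <- as.integer(max_gap)
  if (is.na(max_gap) || max_gap < 0L) stop("max_gap must be >= 0", call. = FALSE)
  if (length(positions) == 0L)
    return(data.frame(start = integer(), end = integer(), count = integer()))
  p <- sort(as.integer(positions))
  grp <- cumsum(c(1L, diff(p) > max_gap))
  data.frame(start = tapply(p, grp, min), end = tapply(p, grp, max),
             count = as.integer(table(grp)), row.names = NULL)
}
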