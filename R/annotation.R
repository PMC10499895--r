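#' Read an annotation track
#'
#' Reads interval annotations (DNA repeats, cryptic recombination signal
#' sequences, ...) either as a 1-based inclusive TSV with columns
#' `start, end, category, name` (matching the catalog's coordinate
#' convention) or as strict BED (0-based half-open, converted on read).
#'
#' @param path file path. `#` and `track` lines are skipped.
#' @param format `"tsv"` (1-based inclusive) or `"bed"`.
#' @return data.frame with columns `start`, `end`, `category`, `name`.
#' @export
read_track <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (format == "tsv") {
    df <- read.delim(text = lines, stringsAsFactors = FALSE)
    stopifnot(all(c("start", "end") %in% names(df)))
  } else {
    df <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
    df <- data.frame(start = df[[2]] + 1L, end = df[[3]],
                     name = if (ncol(df) >= 4) df[[4]] else NA_character_)
  }
  df$category <- df$category %||% "other"
  df$name <- df$name %||% NA_character_
  annotation_track(df$start, df$end, df$category, df$name)
}

#' Construct an annotation track
#'
#' @param start,end 1-based inclusive interval bounds.
#' @param category interval category (`repeat`, `cRSS`, `other`, ...).
#' @param name free-text name (e.g. repeat family).
#' @return data.frame track.
#' @export
annotation_track <- function(start, end, category = "other",
                             name = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start) | is.na(end) | start > end))
    stop("invalid track interval: start must be <= end", call. = FALSE)
  data.frame(start = start, end = end,
             category = rep_len(as.character(category), length(start)),
             name = rep_len(as.character(name), length(start)),
             stringsAsFactors = FALSE)
}

#' Classify a position against an annotation track
#'
#' A position is `inside` if any interval contains it, `vicinity` if it lies
#' within `vicinity_5p` bp upstream of an interval start or `vicinity_3p` bp
#' downstream of an interval end (but inside none), else `outside`. The
#' symmetric default (+/- `vicinity` bp) is the rule used for cryptic RSS
#' sites; the repeat rule "in or immediately 3' of" is expressed with
#' `vicinity_5p = 0`.
#'
#' @param position single 1-based coordinate.
#' @param track data.frame from [annotation_track()].
#' @param vicinity symmetric vicinity in bp (default 30).
#' @param vicinity_5p,vicinity_3p asymmetric override of `vicinity`.
#' @return list with `status` (`inside`/`vicinity`/`outside`) and `matches`
#'   (row indices of matched intervals).
#' @export
classify_position <- function(position, track, vicinity = 30,
                              vicinity_5p = vicinity, vicinity_3p = vicinity) {
  if (vicinity_5p < 0 || vicinity_3p < 0)
    stop("vicinity must be >= 0", call. = FALSE)
  position <- as.integer(position)
  if (nrow(track) == 0L) return(list(status = "outside", matches = integer()))
  inside <- which(track$start <= position & position <= track$end)
  if (length(inside)) return(list(status = "inside", matches = inside))
  near <- which((position < track$start &
                   position >= track$start - vicinity_5p) |
                (position > track$end &
                   position <= track$end + vicinity_3p))
  if (length(near)) return(list(status = "vicinity", matches = near))
  list(status = "outside", matches = integer())
}

#' Vectorized [classify_position()]
#'
#' @inheritParams classify_position
#' @param positions integer vector of coordinates.
#' @return character vector of statuses.
#' @export
classify_positions <- function(positions, track, vicinity = 30,
                               vicinity_5p = vicinity, vicinity_3p = vicinity) {
  vapply(positions, function(p)
    classify_position(p, track, vicinity, vicinity_5p, vicinity_3p)$status,
    character(1))
}

#' Fraction of positions overlapping a track
#'
#' Counts positions classified inside or in the vicinity of track intervals
#' and reports the percentage (1 decimal, half-away-from-zero).
#'
#' @inheritParams classify_positions
#' @return list with `count`, `total`, `percentage`.
#' @export
fraction_overlapping <- function(positions, track, vicinity = 30,
                                 vicinity_5p = vicinity,
                                 vicinity_3p = vicinity) {
  if (length(positions) == 0L) stop("positions must be non-empty", call. = FALSE)
  st <- classify_positions(positions, track, vicinity, vicinity_5p, vicinity_3p)
  n <- sum(st != "outside")
  list(count = n, total = length(positions),
       percentage = percent(n, length(positions), 1))
}

#' Track coverage of an intron
#'
#' Merges overlapping intervals and reports covered bases and the percentage
#' of the intron covered (1 decimal, half-away-from-zero).
#'
#' @param track data.frame from [annotation_track()].
#' @param space an [intron_space()].
#' @return list with `covered_bp` and `percentage`.
#' @export
track_coverage <- function(track, space) {
  stopifnot(inherits(space, "intron_space"))
  if (nrow(track) == 0L) return(list(covered_bp = 0L, percentage = 0))
  if (any(track$start < 1L | track$end > space$length))
    stop("track interval outside ", space$name, call. = FALSE)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(track$start, track$end))))
  list(covered_bp = covered, percentage = percent(covered, space$length, 1))
}
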