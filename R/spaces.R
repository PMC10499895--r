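#' Intron coordinate spaces
#'
#' An `intron_space` ties a 1-based, inclusive intron-relative coordinate
#' system to a genomic interval. Breakpoints in the catalog are recorded
#' intron-relative; conversion to genomic coordinates supports both
#' anchorings because the source data do not state which intron end is
#' position 1 (TCF3 is transcribed from the chromosome 19 minus strand).
#'
#' @param name label for the space.
#' @param chrom chromosome label.
#' @param genomic_start,genomic_end 1-based inclusive genomic bounds.
#' @return an object of class `intron_space`.
#' @examples
#' sp <- tcf3_intron16()
#' sp$length  # 3289
#' @export
intron_space <- function(name, chrom, genomic_start, genomic_end) {
  stopifnot(is.character(name), is.character(chrom))
  genomic_start <- as.integer(genomic_start)
  genomic_end <- as.integer(genomic_end)
  if (is.na(genomic_start) || is.na(genomic_end) || genomic_end < genomic_start)
    stop("invalid genomic bounds for intron space '", name, "'", call. = FALSE)
  structure(
    list(name = name, chrom = chrom,
         genomic_start = genomic_start, genomic_end = genomic_end,
         length = genomic_end - genomic_start + 1L),
    class = "intron_space")
}

#' @rdname intron_space
#' @export
tcf3_intron16 <- function() {
  intron_space("TCF3_intron16", "chr19", 1615822L, 1619110L)
}

#' @rdname intron_space
#' @export
pbx1_intron2 <- function() {
  intron_space("PBX1_intron2", "chr1", 164563312L, 164792493L)
}

#' @export
print.intron_space <- function(x, ...) {
  cat(sprintf("<intron_space> %s  %s:%d-%d (%d bp)\n",
              x$name, x$chrom, x$genomic_start, x$genomic_end, x$length))
  invisible(x)
}

#' Convert intron-relative positions to genomic coordinates
#'
#' Plus-anchored: intron position 1 is `genomic_start`. Minus-anchored:
#' position 1 is `genomic_end` (counting inward from the other intron end).
#' Both modes are bijections of `1:space$length`.
#'
#' @param space an [intron_space()].
#' @param position integer vector of 1-based intron-relative positions.
#' @param mode anchoring mode.
#' @return data.frame with columns `chrom` and `genomic`.
#' @export
intron_to_genomic <- function(space, position,
                              mode = c("plus-anchored", "minus-anchored")) {
  stopifnot(inherits(space, "intron_space"))
  mode <- match.arg(mode)
  position <- as.integer(position)
  bad <- is.na(position) | position < 1L | position > space$length
  if (any(bad))
    stop("position out of range 1..", space$length, ": ",
         paste(position[bad], collapse = ", "), call. = FALSE)
  genomic <- if (mode == "plus-anchored") space$genomic_start + position - 1L
             else space$genomic_end - position + 1L
  data.frame(chrom = space$chrom, genomic = genomic)
}

#' Inverse of [intron_to_genomic()]
#'
#' @inheritParams intron_to_genomic
#' @param genomic integer vector of genomic coordinates within the space.
#' @return integer vector of intron-relative positions.
#' @export
genomic_to_intron <- function(space, genomic,
                              mode = c("plus-anchored", "minus-anchored")) {
  stopifnot(inherits(space, "intron_space"))
  mode <- match.arg(mode)
  genomic <- as.integer(genomic)
  bad <- is.na(genomic) | genomic < space$genomic_start | genomic > space$genomic_end
  if (any(bad))
    stop("genomic coordinate outside ", space$name, call. = FALSE)
  if (mode == "plus-anchored") genomic - space$genomic_start + 1L
  else space$genomic_end - genomic + 1L
}
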