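#' In silico restriction digest
#'
#' Cuts a sequence at every occurrence of the enzyme's recognition site
#' (IUPAC-aware; for non-palindromic sites both strands are scanned), with
#' the cut placed `cut_offset_top` bases into the site on the top strand.
#' A linear molecule with n cut positions yields n+1 fragments; a circular
#' one yields n fragments (or the intact circle for n = 0). Fragment
#' sequences always concatenate back to the parent.
#'
#' @param seq parent sequence (character or `DNAString`).
#' @param enzyme a [restriction_enzyme()].
#' @param topology `"linear"` or `"circular"`.
#' @return data.frame of class `digest_fragments` with columns `start`,
#'   `end` (parent coordinates; a circular wrap-around fragment has
#'   `start > end`), `length`, `seq`, `left_end`, `right_end` (`"site"`,
#'   `"end"`, or `"circular"`).
#' @examples
#' digest("AAGCATGCTT", restriction_enzyme("SphI", "GCATGC", 5, 1))
#' @export
digest <- function(seq, enzyme, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  seq <- .as_seq(seq)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  L <- nchar(seq)
  cuts <- .cut_positions(seq, enzyme)

  if (topology == "linear") {
    cuts <- cuts[cuts >= 1L & cuts < L]
    bounds <- c(0L, cuts, L)
    frags <- data.frame(
      start = bounds[-length(bounds)] + 1L, end = bounds[-1L])
    frags$left_end <- ifelse(frags$start == 1L, "end", "site")
    frags$right_end <- ifelse(frags$end == L, "end", "site")
  } else {
    cuts <- sort(unique(ifelse(cuts %% L == 0L, L, cuts %% L)))
    if (length(cuts) == 0L) {
      frags <- data.frame(start = 1L, end = L, left_end = "circular",
                          right_end = "circular")
    } else {
      starts <- c(cuts[length(cuts)] %% L + 1L, cuts[-length(cuts)] + 1L)
      frags <- data.frame(start = starts, end = cuts,
                          left_end = "site", right_end = "site")
    }
  }
  frags$length <- ifelse(frags$end >= frags$start,
                         frags$end - frags$start + 1L,
                         L - frags$start + 1L + frags$end)
  frags$seq <- vapply(seq_len(nrow(frags)), function(i) {
    if (frags$end[i] >= frags$start[i])
      substr(seq, frags$start[i], frags$end[i])
    else paste0(substr(seq, frags$start[i], L), substr(seq, 1, frags$end[i]))
  }, character(1))
  frags <- frags[c("start", "end", "length", "seq", "left_end", "right_end")]
  attr(frags, "topology") <- topology
  attr(frags, "enzyme") <- enzyme$name
  class(frags) <- c("digest_fragments", "data.frame")
  frags
}

# top-strand cut positions ("cut after base i") for all site occurrences
.cut_positions <- function(seq, enzyme) {
  subj <- Biostrings::DNAString(seq)
  fixed <- !is_degenerate(enzyme)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(enzyme$recognition),
                                   subj, fixed = fixed)
  cuts <- IRanges::start(hits) - 1L + enzyme$cut_offset_top
  if (!is_palindromic(enzyme)) {
    rc <- Biostrings::reverseComplement(
      Biostrings::DNAString(enzyme$recognition))
    hits2 <- Biostrings::matchPattern(rc, subj, fixed = fixed)
    # a site on the minus strand: top-strand cut mirrors the bottom offset
    cuts <- c(cuts, IRanges::start(hits2) - 1L +
                nchar(enzyme$recognition) - enzyme$cut_offset_bottom)
  }
  sort(unique(cuts))
}
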