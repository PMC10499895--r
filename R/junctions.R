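#' Characterize a fusion junction
#'
#' Given a derivative (fusion) sequence anchored so that it begins with a
#' prefix of the donor reference and ends with a suffix of the acceptor
#' reference, computes the breakpoint coordinates, junction microhomology
#' and any inserted sequence. With `x` the longest common prefix of
#' (der, donor) and `y` the longest common suffix of (der, acceptor):
#' if `x + y >= |der|` the junction carries `x + y - |der|` bases of
#' microhomology (attributable to either side, so the breakpoint is
#' reported as a coordinate range); otherwise the bases
#' `der[x+1 .. |der|-y]` are an insertion and microhomology is 0.
#' Microhomology and insertion are mutually exclusive by construction.
#'
#' The reported `donor_break` / `acceptor_break` use the 5'-most donor
#' coordinate convention; `donor_range` / `acceptor_range` give the full
#' ambiguity interval (width = microhomology).
#'
#' @param der_seq derivative sequence spanning the junction.
#' @param donor_ref donor-side reference (shares a prefix with `der_seq`).
#' @param acceptor_ref acceptor-side reference (shares a suffix).
#' @param foreign_db optional named character vector of foreign sequences
#'   for insert classification.
#' @param min_insert_len minimum insert length for inversion/foreign
#'   classification (below it every insert is non-template); default 10.
#' @return list of class `junction_call`: `donor_break`, `acceptor_break`,
#'   `donor_range`, `acceptor_range`, `microhomology_len`, `inserted_seq`,
#'   `insert_class` (`none`, `non-template`, `inverted-segment`, `foreign`).
#' @examples
#' # donor prefix TTGA + non-template GTA + acceptor suffix AATT
#' characterize_junction("TTGAGTAAATT", "TTGACCAT", "CCGGAATT")
#' @export
characterize_junction <- function(der_seq, donor_ref, acceptor_ref,
                                  foreign_db = NULL, min_insert_len = 10) {
  der <- Biostrings::DNAString(.as_seq(der_seq))
  don <- Biostrings::DNAString(.as_seq(donor_ref))
  acc <- Biostrings::DNAString(.as_seq(acceptor_ref))
  L <- length(der)
  x <- Biostrings::lcprefix(der, don)
  y <- Biostrings::lcsuffix(der, acc)
  if (x == 0L || y == 0L)
    stop("anchoring error: derivative does not share a ",
         if (x == 0L) "prefix with the donor" else "suffix with the acceptor",
         " reference", call. = FALSE)

  if (x + y >= L) {
    mh <- x + y - L
    a_min <- length(acc) - y + 1L
    call <- list(donor_break = x - mh, acceptor_break = a_min,
                 donor_range = c(x - mh, x),
                 acceptor_range = c(a_min, a_min + mh),
                 microhomology_len = mh, inserted_seq = "",
                 insert_class = "none")
  } else {
    ins <- as.character(Biostrings::subseq(der, x + 1L, L - y))
    call <- list(donor_break = x, acceptor_break = length(acc) - y + 1L,
                 donor_range = c(x, x),
                 acceptor_range = rep(length(acc) - y + 1L, 2L),
                 microhomology_len = 0L, inserted_seq = ins,
                 insert_class = classify_insert(ins, donor_ref, acceptor_ref,
                                                foreign_db, min_insert_len))
  }
  structure(call, class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("<junction_call> donor %d | acceptor %d; mh %d bp%s\n",
              x$donor_break, x$acceptor_break, x$microhomology_len,
              if (nzchar(x$inserted_seq))
                sprintf("; insert %d bp (%s)", nchar(x$inserted_seq),
                        x$insert_class) else ""))
  invisible(x)
}

#' Classify an inserted junction sequence
#'
#' An insert of at least `min_len` bp is an `inverted-segment` if it equals
#' the reverse complement of a contiguous stretch of either parental
#' reference (templated inversion, as in a patient whose junction carried a
#' 788 bp inverted PBX1 segment), `foreign` if it occurs within a sequence
#' of `foreign_db` (e.g. an insert captured from another chromosome), and
#' `non-template` otherwise. Inserts below `min_len` are always called
#' non-template: short matches arise by chance.
#'
#' @param inserted_seq non-empty insert sequence.
#' @param donor_ref,acceptor_ref parental references.
#' @param foreign_db optional named character vector of candidate foreign
#'   source sequences.
#' @param min_len minimum length for templated classification (default 10).
#' @return one of `"inverted-segment"`, `"foreign"`, `"non-template"`.
#' @export
classify_insert <- function(inserted_seq, donor_ref, acceptor_ref,
                            foreign_db = NULL, min_len = 10) {
  ins <- .as_seq(inserted_seq, "inserted_seq")
  if (nchar(ins) < min_len) return("non-template")
  rc <- revcomp(ins)
  for (ref in c(.as_seq(donor_ref), .as_seq(acceptor_ref)))
    if (grepl(rc, ref, fixed = TRUE)) return("inverted-segment")
  for (f in foreign_db) {
    f <- .as_seq(f)
    if (grepl(ins, f, fixed = TRUE) || grepl(revcomp(ins), f, fixed = TRUE))
      return("foreign")
  }
  "non-template"
}
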