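#' Restriction enzyme definition
#'
#' @param name enzyme name.
#' @param recognition recognition site, IUPAC string 5'->3'.
#' @param cut_offset_top,cut_offset_bottom cut positions within the site in
#'   bases from its 5' end on the respective strand (`0..nchar(recognition)`).
#'   E.g. SphI GCATG|C has `cut_offset_top = 5`, `cut_offset_bottom = 1`.
#' @return object of class `restriction_enzyme`.
#' @examples
#' sphi <- restriction_enzyme("SphI", "GCATGC", 5, 1)
#' is_palindromic(sphi); is_sticky(sphi)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top,
                               cut_offset_bottom) {
  recognition <- .as_seq(recognition, "recognition site")
  cut_offset_top <- as.integer(cut_offset_top)
  cut_offset_bottom <- as.integer(cut_offset_bottom)
  len <- nchar(recognition)
  if (anyNA(c(cut_offset_top, cut_offset_bottom)) ||
      cut_offset_top < 0L || cut_offset_top > len ||
      cut_offset_bottom < 0L || cut_offset_bottom > len)
    stop("cut offsets must lie in 0..", len, call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = cut_offset_top,
                 cut_offset_bottom = cut_offset_bottom),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @param enzyme a `restriction_enzyme`.
#' @export
is_palindromic <- function(enzyme) {
  enzyme$recognition == revcomp(enzyme$recognition)
}

#' @rdname restriction_enzyme
#' @export
is_degenerate <- function(enzyme) grepl("[^ACGT]", enzyme$recognition)

#' @rdname restriction_enzyme
#' @export
is_sticky <- function(enzyme) enzyme$cut_offset_top != enzyme$cut_offset_bottom

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset_top), "|",
                 substr(x$recognition, x$cut_offset_top + 1,
                        nchar(x$recognition)))
  cat(sprintf("<restriction_enzyme> %s %s (top cut %d, bottom cut %d)\n",
              x$name, site, x$cut_offset_top, x$cut_offset_bottom))
  invisible(x)
}

#' Load a restriction enzyme database
#'
#' TSV with columns `name, recognition, cut_offset_top, cut_offset_bottom`
#' (`#` comments allowed). [lri_enzymes()] returns the packaged SphI / BamHI
#' / TaqI set used for long range-inverse PCR.
#'
#' @param path TSV file.
#' @return named list of [restriction_enzyme()] objects.
#' @export
load_enzyme_db <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_offset_top",
                  "cut_offset_bottom") %in% names(df)))
  setNames(lapply(seq_len(nrow(df)), function(i)
    restriction_enzyme(df$name[i], df$recognition[i], df$cut_offset_top[i],
                       df$cut_offset_bottom[i])), df$name)
}

#' @rdname load_enzyme_db
#' @export
lri_enzymes <- function() {
  load_enzyme_db(fusionbreak_example("lri_enzymes.tsv"))
}

#' PCR primer
#'
#' @param name primer name.
#' @param sequence 5'->3' A/C/G/T sequence, length >= 15.
#' @return object of class `pcr_primer`.
#' @export
primer <- function(name, sequence) {
  sequence <- .as_seq(sequence, "primer sequence")
  .check_acgt(sequence, paste0("primer ", name))
  if (nchar(sequence) < 15L)
    stop("primer ", name, " shorter than 15 nt", call. = FALSE)
  structure(list(name = name, sequence = sequence), class = "pcr_primer")
}

#' @export
print.pcr_primer <- function(x, ...) {
  cat(sprintf("<pcr_primer> %s 5'-%s-3' (%d nt)\n", x$name, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' Load an oligonucleotide database
#'
#' TSV with columns `name, sequence, role, label`. [lri_oligos()] returns
#' the packaged oligo set: long range-inverse PCR primers, the two multiplex
#' long-range panels, and the generic qPCR forward primer/probe.
#'
#' @param path TSV file.
#' @param role optional filter on the `role` column.
#' @return named list of [primer()] objects.
#' @export
load_primers <- function(path, role = NULL) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence") %in% names(df)))
  if (!is.null(role) && "role" %in% names(df)) df <- df[df$role %in% role, ]
  setNames(lapply(seq_len(nrow(df)), function(i)
    primer(df$name[i], df$sequence[i])), df$name)
}

#' @rdname load_primers
#' @export
lri_oligos <- function(role = NULL) {
  load_primers(fusionbreak_example("oligos.tsv"), role = role)
}
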