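#' @importFrom Biostrings DNAString DNAStringSet reverseComplement matchPattern
#' @importFrom IRanges IRanges reduce width start end
#' @importFrom stats lm coef cor median rbinom rgeom runif setNames
#' @importFrom utils read.delim read.csv write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: 0.5 always rounds
#' away from zero, unlike [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a DNA string
#'
#' @param x single character string over the IUPAC DNA alphabet.
#' @return character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# coerce character / DNAString to plain uppercase character
.as_seq <- function(x, what = "sequence") {
  if (inherits(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || nchar(x) < 1L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  toupper(x)
}

.check_acgt <- function(x, what = "sequence") {
  if (grepl("[^ACGT]", x))
    stop(what, " contains non-ACGT symbols", call. = FALSE)
  invisible(x)
}

# evaluate expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
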