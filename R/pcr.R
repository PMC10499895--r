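#' Locate exact primer binding sites
#'
#' Reports every exact full-length occurrence of the primer on the plus
#' strand and of its reverse complement on the minus strand (mismatch
#' tolerance is deliberately out of scope: the assay primers are long and
#' specific). `pos5` is the plus-strand coordinate of the primer's 5' base:
#' the site start for plus-strand hits and the site end for minus-strand
#' hits (the primer extends leftward in plus coordinates).
#'
#' @param seq template sequence.
#' @param primer a [primer()].
#' @return data.frame with `pos5`, `strand` (`+`/`-`), `start`, `end`.
#' @export
find_primer_sites <- function(seq, primer) {
  seq <- .as_seq(seq)
  stopifnot(inherits(primer, "pcr_primer"))
  subj <- Biostrings::DNAString(seq)
  plus <- Biostrings::matchPattern(primer$sequence, subj)
  minus <- Biostrings::matchPattern(revcomp(primer$sequence), subj)
  out <- rbind(
    data.frame(pos5 = IRanges::start(plus),
               strand = rep("+", length(plus)),
               start = IRanges::start(plus), end = IRanges::end(plus)),
    data.frame(pos5 = IRanges::end(minus),
               strand = rep("-", length(minus)),
               start = IRanges::start(minus), end = IRanges::end(minus)))
  out[order(out$start), , drop = FALSE]
}

.unique_site <- function(seq, primer) {
  s <- find_primer_sites(seq, primer)
  if (nrow(s) > 1L)
    stop("primer ", primer$name, " binds ", nrow(s),
         " times: ambiguous", call. = FALSE)
  s
}

#' Predict an inverse-PCR product on a self-ligated fragment
#'
#' The fragment is assumed to circularize via its two cohesive enzyme ends.
#' A product exists iff the forward primer binds the plus strand once, the
#' reverse primer binds the minus strand once, and the two sites are
#' divergent on the linear fragment (reverse site 5' of the forward site),
#' so that amplification runs outward across the ligation junction. The
#' product size counts the bases on the circular path from the forward
#' primer's 5' base through the junction to the reverse primer's 5' base,
#' inclusive; it is invariant under rotation of the linearization point.
#'
#' @param fragment fragment sequence (character), or one row of a
#'   [digest()] result, in which case both ends must be enzyme junctions.
#' @param forward,reverse [primer()] objects.
#' @return list of class `amplicon` with `forward`, `reverse`, `size`,
#'   `span` (plus-strand 5' coordinates of the two primers) and
#'   `contains_junction = TRUE`; or `NULL` if no product.
#' @export
inverse_pcr_product <- function(fragment, forward, reverse) {
  if (is.data.frame(fragment)) {
    stopifnot(nrow(fragment) == 1L)
    if (!all(c(fragment$left_end, fragment$right_end) %in%
             c("site", "circular")))
      stop("fragment has a free molecule end and cannot self-ligate",
           call. = FALSE)
    fragment <- fragment$seq
  }
  fragment <- .as_seq(fragment)
  L <- nchar(fragment)
  fs <- .unique_site(fragment, forward)
  rs <- .unique_site(fragment, reverse)
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(NULL)
  if (fs$strand != "+" || rs$strand != "-") return(NULL)
  if (rs$pos5 >= fs$pos5) return(NULL)  # convergent: ordinary PCR, no junction
  structure(list(forward = forward$name, reverse = reverse$name,
                 size = L - fs$pos5 + 1L + rs$pos5,
                 span = c(forward_5p = fs$pos5, reverse_5p = rs$pos5),
                 contains_junction = TRUE),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s/%s %d bp%s\n", x$forward, x$reverse, x$size,
              if (isTRUE(x$contains_junction)) " (spans junction)" else ""))
  invisible(x)
}

# index of the digest fragment containing plus-coordinate interval [s, e]
.fragment_index <- function(frags, s, e) {
  i <- which(frags$start <= s & frags$end >= e &
               frags$end >= frags$start)
  if (length(i)) i[1L] else NA_integer_
}

#' Predict control bands from unrearranged DNA
#'
#' For each primer pair: digest the reference, find the fragment carrying
#' both primer binding sites, self-ligate it, and compute the inverse-PCR
#' product size. This reproduces the "control bands" that normal
#' (untranslocated) DNA yields in long range-inverse PCR. Primer strand
#' orientation is resolved automatically (the pair is tried in both
#' forward/reverse roles). Pairs whose primers are absent, on different
#' fragments, or on a non-circularizable terminal fragment are reported
#' `NA`, with the reason in the `"reasons"` attribute.
#'
#' @param reference_seq reference sequence covering the primer region and
#'   flanking restriction sites.
#' @param enzyme a [restriction_enzyme()].
#' @param primer_pairs list of two-element lists of [primer()] objects.
#' @return named numeric vector of product sizes (names `"F/R"`).
#' @export
control_band_sizes <- function(reference_seq, enzyme, primer_pairs) {
  reference_seq <- .as_seq(reference_seq)
  frags <- digest(reference_seq, enzyme, "linear")
  sizes <- numeric(0)
  reasons <- character(0)
  for (pair in primer_pairs) {
    a <- pair[[1]]; b <- pair[[2]]
    key <- paste(a$name, b$name, sep = "/")
    sa <- find_primer_sites(reference_seq, a)
    sb <- find_primer_sites(reference_seq, b)
    if (nrow(sa) != 1L || nrow(sb) != 1L) {
      sizes[key] <- NA_real_
      reasons[key] <- "primer absent or multiply binding"
      next
    }
    ia <- .fragment_index(frags, sa$start, sa$end)
    ib <- .fragment_index(frags, sb$start, sb$end)
    if (is.na(ia) || is.na(ib) || ia != ib) {
      sizes[key] <- NA_real_
      reasons[key] <- "primers not on the same fragment"
      next
    }
    frag <- frags[ia, ]
    amp <- tryCatch(
      inverse_pcr_product(frag, a, b) %||% inverse_pcr_product(frag, b, a),
      error = function(e) NULL)
    if (is.null(amp)) {
      sizes[key] <- NA_real_
      reasons[key] <- "no divergent plus/minus configuration on fragment"
    } else {
      sizes[key] <- amp$size
      reasons[key] <- "ok"
    }
  }
  attr(sizes, "reasons") <- reasons
  sizes
}

#' Per-enzyme breakpoint detectability
#'
#' A derivative-chromosome junction is detectable by long range-inverse PCR
#' with a given enzyme iff the digest fragment that carries both primer
#' binding sites also contains the junction position, the fragment can
#' self-ligate (no free molecule end), and the predicted inverse-PCR
#' product does not exceed `max_size`. This captures, e.g., why an enzyme
#' cutting between the primer region and the intron end cannot detect
#' breakpoints near the intron end.
#'
#' @param der_seq derivative chromosome sequence.
#' @param junction_pos 1-based coordinate of the last base 5' of the fusion
#'   junction on `der_seq`.
#' @param enzyme a [restriction_enzyme()].
#' @param forward,reverse [primer()] objects.
#' @param max_size maximum amplifiable product (default 10000 bp; the
#'   largest band validated in practice was 7567 bp).
#' @return list with `detectable`, `size` (or `NA`), `reason`.
#' @export
breakpoint_detectability <- function(der_seq, junction_pos, enzyme, forward,
                                     reverse, max_size = 10000) {
  der_seq <- .as_seq(der_seq)
  junction_pos <- as.integer(junction_pos)
  if (junction_pos < 1L || junction_pos > nchar(der_seq))
    stop("junction_pos outside der_seq", call. = FALSE)
  frags <- digest(der_seq, enzyme, "linear")
  sf <- find_primer_sites(der_seq, forward)
  sr <- find_primer_sites(der_seq, reverse)
  if (nrow(sf) != 1L || nrow(sr) != 1L)
    return(list(detectable = FALSE, size = NA_real_,
                reason = "primer absent or multiply binding"))
  i <- .fragment_index(frags, sf$start, sf$end)
  j <- .fragment_index(frags, sr$start, sr$end)
  if (is.na(i) || is.na(j) || i != j)
    return(list(detectable = FALSE, size = NA_real_,
                reason = "primers not on same fragment"))
  frag <- frags[i, ]
  if (junction_pos < frag$start || junction_pos > frag$end)
    return(list(detectable = FALSE, size = NA_real_,
                reason = "junction not on primer fragment"))
  if (!all(c(frag$left_end, frag$right_end) == "site"))
    return(list(detectable = FALSE, size = NA_real_,
                reason = "fragment cannot self-ligate"))
  amp <- tryCatch(
    inverse_pcr_product(frag, forward, reverse) %||%
      inverse_pcr_product(frag, reverse, forward),
    error = function(e) NULL)
  if (is.null(amp))
    return(list(detectable = FALSE, size = NA_real_,
                reason = "no divergent primer configuration"))
  if (amp$size > max_size)
    return(list(detectable = FALSE, size = amp$size,
                reason = sprintf("product %d bp exceeds max %d bp",
                                 amp$size, as.integer(max_size))))
  list(detectable = TRUE, size = amp$size, reason = "ok")
}

#' Predict multiplex long-range PCR products
#'
#' One shared forward primer is combined with a panel of reverse primers
#' tiled across a breakpoint cluster region; a product is predicted for
#' every panel primer whose minus-strand site lies downstream of the
#' forward site within `max_size`. When `junction_pos` is given, only
#' products bracketing the fusion junction are returned (the configuration
#' that actually reports a breakpoint).
#'
#' @param der_seq template (derivative chromosome) sequence.
#' @param forward shared forward [primer()].
#' @param reverse_panel list of reverse [primer()]s (5'->3'; their reverse
#'   complements are sought on the template plus strand).
#' @param max_size maximum product size (default 10000 bp).
#' @param junction_pos optional junction coordinate on `der_seq`.
#' @return data.frame with one row per predicted product (`forward`,
#'   `reverse`, `size`, `start`, `end`, `contains_junction`), sorted by size.
#' @export
multiplex_products <- function(der_seq, forward, reverse_panel,
                               max_size = 10000, junction_pos = NULL) {
  der_seq <- .as_seq(der_seq)
  sf <- find_primer_sites(der_seq, forward)
  sf <- sf[sf$strand == "+", , drop = FALSE]
  empty <- data.frame(forward = character(), reverse = character(),
                      size = integer(), start = integer(), end = integer(),
                      contains_junction = logical())
  if (nrow(sf) != 1L) return(empty)
  rows <- list()
  for (rp in reverse_panel) {
    sr <- find_primer_sites(der_seq, rp)
    sr <- sr[sr$strand == "-", , drop = FALSE]
    if (nrow(sr) != 1L) next
    if (sr$pos5 <= sf$pos5) next
    size <- sr$pos5 - sf$pos5 + 1L
    if (size > max_size) next
    cj <- if (is.null(junction_pos)) NA else
      (sf$pos5 <= junction_pos && junction_pos < sr$pos5)
    if (!is.null(junction_pos) && !cj) next
    rows[[length(rows) + 1L]] <- data.frame(
      forward = forward$name, reverse = rp$name, size = size,
      start = sf$pos5, end = sr$pos5, contains_junction = cj)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$size), , drop = FALSE]
}

#' Screen restriction enzymes for inverse-PCR suitability
#'
#' An enzyme passes iff its recognition site is palindromic, free of
#' degenerate (non-ACGT) symbols, cut with offset ends (sticky), short
#' enough to make it a frequent cutter, and the digest leaves at least one
#' cut on each side of the target region such that the fragment containing
#' the region stays within the maximum amplifiable size.
#'
#' @param enzyme_db named list of [restriction_enzyme()]s.
#' @param region_seq sequence containing the target region.
#' @param region one-row data.frame from [region()] (coordinates on
#'   `region_seq`).
#' @param max_site_len frequent-cutter threshold on recognition length
#'   (default 6: admits 4- and 6-cutters).
#' @param max_fragment maximum tolerated fragment length containing the
#'   region (default 10000 bp).
#' @return data.frame with one row per enzyme, per-criterion logicals,
#'   flanking cut distances, fragment length and overall `pass`; passing
#'   enzymes first, ranked by fragment length.
#' @export
screen_enzymes <- function(enzyme_db, region_seq, region, max_site_len = 6,
                           max_fragment = 10000) {
  region_seq <- .as_seq(region_seq)
  stopifnot(is.data.frame(region), nrow(region) == 1L,
            region$end <= nchar(region_seq))
  rows <- lapply(enzyme_db, function(e) {
    out <- data.frame(
      name = e$name, recognition = e$recognition,
      palindromic = is_palindromic(e), non_degenerate = !is_degenerate(e),
      sticky = is_sticky(e),
      frequent_cutter = nchar(e$recognition) <= max_site_len,
      dist5 = NA_integer_, dist3 = NA_integer_, fragment_len = NA_integer_,
      flanked = FALSE)
    if (out$palindromic && out$non_degenerate && out$sticky &&
        out$frequent_cutter) {
      cuts <- .cut_positions(region_seq, e)
      left <- cuts[cuts < region$start]
      right <- cuts[cuts >= region$end]
      if (length(left) && length(right)) {
        out$dist5 <- region$start - max(left)
        out$dist3 <- min(right) - region$end
        out$fragment_len <- min(right) - max(left)
        out$flanked <- out$fragment_len <= max_fragment
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  out$pass <- out$palindromic & out$non_degenerate & out$sticky &
    out$frequent_cutter & out$flanked
  out <- out[order(-out$pass, out$fragment_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}
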