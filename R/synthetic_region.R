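#' Synthetic stand-in for the TCF3 breakpoint-region reference
#'
#' Builds, deterministically, a SYNTHETIC ~13.5 kb sequence that emulates
#' the restriction-map geometry of the genomic TCF3 breakpoint region used
#' for long range-inverse PCR: the five LRI primers are planted once each
#' (forward primers on the plus strand, reverse primers on the minus
#' strand, divergently oriented), and one SphI, BamHI and TaqI site is
#' planted on each side of the primer block at distances derived from the
#' six published control-band sizes (3308 / 2131 / 5026 / 3849 / 7567 /
#' 6390 bp; the per-enzyme F2-F6 differences are all 1177 bp, fixing a
#' consistent layout). All accidental occurrences of the three recognition
#' sites are scrubbed, so digesting, self-ligating and amplifying this
#' sequence reproduces exactly the six control bands. This is NOT genomic
#' sequence; it is a geometry-faithful stand-in for environments without
#' access to the reference assembly.
#'
#' @param seed integer seed for the background sequence.
#' @return character sequence with attribute `"layout"`, a data.frame of
#'   planted feature coordinates.
#' @export
synthetic_tcf3_region <- function(seed = 20260909) {
  oligos <- lri_oligos(role = "lri")
  layout <- data.frame(
    feature = c("TaqI_site_5p", "SphI_site_5p", "BamHI_site_5p",
                "TCF3-R4", "TCF3-R5", "TaqI-R",
                "TCF3-F2", "TCF3-F6",
                "BamHI_site_3p", "SphI_site_3p", "TaqI_site_3p"),
    start = c(3699L, 3795L, 3899L, 3972L, 4072L, 4175L, 6000L, 7177L,
              9206L, 10720L, 13065L),
    strand = c("+", "+", "+", "-", "-", "-", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  seqs <- c(TaqI_site_5p = "TCGA", SphI_site_5p = "GCATGC",
            BamHI_site_5p = "GGATCC",
            `TCF3-R4` = revcomp(oligos[["TCF3-R4"]]$sequence),
            `TCF3-R5` = revcomp(oligos[["TCF3-R5"]]$sequence),
            `TaqI-R` = revcomp(oligos[["TaqI-R"]]$sequence),
            `TCF3-F2` = oligos[["TCF3-F2"]]$sequence,
            `TCF3-F6` = oligos[["TCF3-F6"]]$sequence,
            BamHI_site_3p = "GGATCC", SphI_site_3p = "GCATGC",
            TaqI_site_3p = "TCGA")
  layout$end <- layout$start + nchar(seqs[layout$feature]) - 1L

  v <- strsplit(generate_reference(13500L, gc = 0.45, seed = seed), "")[[1L]]
  protected <- logical(length(v))
  for (i in seq_len(nrow(layout))) {
    idx <- layout$start[i]:layout$end[i]
    v[idx] <- strsplit(seqs[[layout$feature[i]]], "")[[1L]]
    protected[idx] <- TRUE
  }

  sites <- c("GCATGC", "GGATCC", "TCGA")
  planted_starts <- split(layout$start, sub("_site.*", "", layout$feature))
  for (iter in 1:100) {
    dirty <- FALSE
    s <- paste(v, collapse = "")
    for (site in sites) {
      enzyme <- c(GCATGC = "SphI", GGATCC = "BamHI", TCGA = "TaqI")[[site]]
      m <- gregexpr(site, s, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) next
      for (st in m) {
        if (st %in% planted_starts[[enzyme]]) next
        idx <- st:(st + nchar(site) - 1L)
        mut <- idx[!protected[idx]]
        if (!length(mut)) stop("cannot scrub site inside protected region")
        j <- mut[1L]
        v[j] <- setdiff(c("A", "C", "G", "T"), v[j])[1L]
        dirty <- TRUE
      }
      if (dirty) break  # re-scan from scratch after mutations
    }
    if (!dirty) break
  }
  out <- paste(v, collapse = "")
  for (nm in names(oligos))
    if (nrow(find_primer_sites(out, oligos[[nm]])) != 1L)
      stop("synthetic region construction failed: primer ", nm,
           " not unique")
  attr(out, "layout") <- layout
  out
}

#' Control-band primer pairs of the long range-inverse PCR assay
#'
#' @return named list: for each enzyme, the list of primer pairs whose
#'   control bands were validated on normal DNA.
#' @export
lri_control_pairs <- function() {
  ol <- lri_oligos(role = "lri")
  list(
    BamHI = list(list(ol[["TCF3-F2"]], ol[["TCF3-R4"]]),
                 list(ol[["TCF3-F6"]], ol[["TCF3-R4"]])),
    SphI = list(list(ol[["TCF3-F2"]], ol[["TCF3-R5"]]),
                list(ol[["TCF3-F6"]], ol[["TCF3-R5"]])),
    TaqI = list(list(ol[["TCF3-F2"]], ol[["TaqI-R"]]),
                list(ol[["TCF3-F6"]], ol[["TaqI-R"]])))
}
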