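# Nearest-neighbor thermodynamics, unified parameters
# (Allawi & SantaLucia 1997): dH kcal/mol, dS cal/(mol K), propagated
# dinucleotides keyed by the top-strand pair; terminal initiation terms per
# A/T and G/C end. Salt correction applied to entropy:
# dS' = dS + 0.368 * (N-1) * ln[Na+].
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
            GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
            TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
            GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            CC = -19.9)

#' Oligonucleotide melting temperature
#'
#' `wallace`: the 2 + 4 rule, `2(A+T) + 4(G+C)` degrees C, adequate for
#' rough screening of short oligos. `nearest-neighbor`: unified
#' nearest-neighbor thermodynamics with entropic monovalent-salt correction
#' and excess-primer approximation,
#' `Tm = 1000 dH / (dS + 0.368 (N-1) ln[Na+] + R ln C) - 273.15`.
#'
#' @param seq A/C/G/T oligo sequence.
#' @param method `"nearest-neighbor"` (default) or `"wallace"`.
#' @param primer_conc molar primer concentration (default 250 nM).
#' @param na_conc molar monovalent cation concentration (default 50 mM).
#' @return melting temperature in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGTACGT", method = "wallace")  # 48
#' @export
melting_temperature <- function(seq, method = c("nearest-neighbor", "wallace"),
                                primer_conc = 250e-9, na_conc = 0.05) {
  method <- match.arg(method)
  seq <- .as_seq(seq, "oligo")
  .check_acgt(seq, "oligo")
  b <- strsplit(seq, "")[[1]]
  if (method == "wallace")
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  n <- length(b)
  if (n < 2L) stop("need at least 2 bases for nearest-neighbor", call. = FALSE)
  pairs <- paste0(b[-n], b[-1L])
  dh <- sum(.NN_DH[pairs])
  ds <- sum(.NN_DS[pairs])
  for (term in b[c(1L, n)]) {
    dh <- dh + if (term %in% c("A", "T")) 2.3 else 0.1
    ds <- ds + if (term %in% c("A", "T")) 4.1 else -2.8
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_conc)
  1000 * dh / (ds + 1.987 * log(primer_conc)) - 273.15
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope) - 1`; a perfect doubling per cycle corresponds to a
#' slope of `-1/log10(2) ~ -3.32` and E = 1. Monotone increasing in slope on
#' the negative axis. Values are returned at full precision; round to 3
#' decimals for reporting.
#'
#' @param slope standard-curve slope in cycles per log10 dilution (< 0).
#' @return efficiency (dimensionless).
#' @examples
#' round(efficiency_from_slope(-3.418), 3)  # 0.961
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0))
    stop("slope must be finite and negative", call. = FALSE)
  10^(-1 / slope) - 1
}

#' Successive Ct differences along a dilution series
#'
#' @param cts Ct values ordered by decreasing concentration; `NA` allowed
#'   (propagates).
#' @return vector of differences `ct[i+1] - ct[i]` (expected ~3.32 for
#'   tenfold dilutions at perfect efficiency).
#' @export
successive_delta_ct <- function(cts) {
  if (length(cts) < 2L) stop("need at least 2 Ct values", call. = FALSE)
  diff(cts)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 concentration; reports slope,
#' intercept, squared Pearson correlation and amplification efficiency.
#'
#' @param points data.frame with columns `log10_concentration` and `ct`
#'   (e.g. 0, -1, ..., -4 for a tenfold dilution series), at least 3 points
#'   over at least 2 distinct concentrations (or exactly 2 points at 2
#'   concentrations). Rows with `NA` Ct are dropped (4-point curves occur).
#' @return list of class `curve_fit`: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `n`.
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("log10_concentration", "ct") %in% names(points)))
  points <- points[!is.na(points$ct) & !is.na(points$log10_concentration), ]
  if (any(points$ct <= 0)) stop("ct values must be positive", call. = FALSE)
  nconc <- length(unique(points$log10_concentration))
  if (nconc < 2L)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  if (nrow(points) < 2L) stop("need at least 2 points", call. = FALSE)
  fit <- lm(ct ~ log10_concentration, data = points)
  slope <- unname(coef(fit)[2L])
  r2 <- if (nrow(points) == 2L) 1
        else cor(points$log10_concentration, points$ct)^2
  structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 efficiency = efficiency_from_slope(slope),
                 n = nrow(points)),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "<curve_fit> slope %.3f, intercept %.2f, R2 %.3f, efficiency %.3f (n=%d)\n",
    x$slope, x$intercept, x$r_squared, x$efficiency, x$n))
  invisible(x)
}

#' Published breakpoint-qPCR standard-curve parameters
#'
#' The packaged table of 15 patient-specific assays: successive Ct
#' differences between tenfold dilutions, slope, R-squared and efficiency
#' as printed (the underlying raw Cts were not published, so slopes are
#' inputs here, not recomputation targets). One patient had a 4-point
#' curve (missing `delta45`).
#'
#' @return data.frame with one row per assay.
#' @export
qpcr_reference_curves <- function() {
  read.csv(fusionbreak_example("qpcr_standard_curves.csv"),
           comment.char = "#", stringsAsFactors = FALSE)
}

#' The generic breakpoint-qPCR assay components
#'
#' The fixed forward primer (TCF3-qF) and dual-labeled 6FAM/BHQ1
#' hybridization probe (TCF3-FAM) sited 5' of the TCF3 intron 16 breakpoint
#' cluster; patient specificity comes solely from the reverse primer.
#'
#' @return list with `forward` and `probe` ([primer()] objects).
#' @export
qpcr_assay_components <- function() {
  ol <- lri_oligos(role = "qpcr")
  list(forward = ol[["TCF3-qF"]], probe = ol[["TCF3-FAM"]])
}

#' Design patient-specific reverse qPCR primers
#'
#' Enumerates reverse-primer candidates 3' of the fusion junction on a
#' patient's derivative sequence, for use with the fixed forward
#' primer/probe 5' of the breakpoint cluster. Candidates must satisfy
#' length, melting temperature and amplicon-size constraints and be
#' specific at assay level: the forward-primer/candidate pair must predict
#' no product within `max_amplicon` on either unrearranged reference. (A
#' reverse primer 3' of the junction necessarily matches the acceptor
#' intron on its own; what must not amplify is normal DNA, which requires
#' both primers on one template.) Returned ranked by distance of Tm from
#' the window midpoint.
#'
#' @param fusion_seq derivative sequence containing forward primer and
#'   probe 5' of the junction.
#' @param junction_pos coordinate of the last base 5' of the junction on
#'   `fusion_seq`.
#' @param donor_ref,acceptor_ref unrearranged reference sequences used for
#'   the specificity check.
#' @param constraints list: `length` (default `c(18, 30)`), `tm` (default
#'   `c(58, 62)` degrees C, nearest-neighbor), `max_amplicon` (default 300
#'   bp), `forward`/`probe` ([primer()]s; default the packaged generic
#'   assay).
#' @return data.frame of candidates (`sequence`, `start`, `end`, `length`,
#'   `tm`, `amplicon_len`), ranked; when empty, the attribute
#'   `"failure_tally"` counts rejections per constraint.
#' @export
design_reverse_primer <- function(fusion_seq, junction_pos, donor_ref,
                                  acceptor_ref, constraints = list()) {
  fusion_seq <- .as_seq(fusion_seq)
  junction_pos <- as.integer(junction_pos)
  cs <- list(length = c(18L, 30L), tm = c(58, 62), max_amplicon = 300L)
  cs[names(constraints)] <- constraints
  comp <- qpcr_assay_components()
  fwd <- cs$forward %||% comp$forward
  prb <- cs$probe %||% comp$probe

  fsite <- find_primer_sites(fusion_seq, fwd)
  fsite <- fsite[fsite$strand == "+", , drop = FALSE]
  if (nrow(fsite) != 1L || fsite$end > junction_pos)
    stop("forward primer not found once on the plus strand 5' of the junction",
         call. = FALSE)
  psite <- find_primer_sites(fusion_seq, prb)
  if (nrow(psite) != 1L || psite$end > junction_pos)
    stop("probe not found once 5' of the junction", call. = FALSE)

  L <- nchar(fusion_seq)
  donor_ref <- .as_seq(donor_ref); acceptor_ref <- .as_seq(acceptor_ref)
  refs <- list(donor = donor_ref, acceptor = acceptor_ref)
  fwd_sites <- lapply(refs, function(r) {
    fs <- find_primer_sites(r, fwd)
    fs$pos5[fs$strand == "+"]
  })
  amplifies_normal <- function(cand) {
    for (nm in names(refs)) {
      if (!length(fwd_sites[[nm]])) next
      cr <- find_primer_sites(refs[[nm]], primer("cand", cand))
      r5 <- cr$pos5[cr$strand == "-"]
      for (f5 in fwd_sites[[nm]])
        if (any(r5 > f5 & r5 - f5 + 1L <= cs$max_amplicon)) return(TRUE)
    }
    FALSE
  }
  tally <- c(no_room = 0L, amplicon = 0L, tm = 0L, specificity = 0L)
  rows <- list()
  for (s in (junction_pos + 1L):L) {
    if (s > L - cs$length[1L] + 1L) { tally["no_room"] <- tally["no_room"] + 1L; break }
    for (len in cs$length[1L]:cs$length[2L]) {
      e <- s + len - 1L
      if (e > L) { tally["no_room"] <- tally["no_room"] + 1L; next }
      amplicon <- e - fsite$pos5 + 1L
      if (amplicon > cs$max_amplicon) { tally["amplicon"] <- tally["amplicon"] + 1L; next }
      cand <- revcomp(substr(fusion_seq, s, e))
      tm <- melting_temperature(cand)
      if (tm < cs$tm[1L] || tm > cs$tm[2L]) { tally["tm"] <- tally["tm"] + 1L; next }
      if (amplifies_normal(cand)) { tally["specificity"] <- tally["specificity"] + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = cand, start = s, end = e, length = len, tm = tm,
        amplicon_len = amplicon)
    }
    if (s - junction_pos > cs$max_amplicon) break
  }
  if (!length(rows)) {
    out <- data.frame(sequence = character(), start = integer(),
                      end = integer(), length = integer(), tm = numeric(),
                      amplicon_len = integer())
    attr(out, "failure_tally") <- tally
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$tm - mean(cs$tm))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
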