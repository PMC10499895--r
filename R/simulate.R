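#' Generate a random reference sequence
#'
#' I.i.d. bases with `P(G or C) = gc`, reproducible for a fixed seed. RNG
#' state is restored on exit; all simulator randomness flows through
#' explicit seeds.
#'
#' @param length sequence length in bp (>= 1).
#' @param gc GC fraction in `[0, 1]` (default 0.4, intron-like).
#' @param seed optional integer seed.
#' @return character sequence.
#' @export
generate_reference <- function(length, gc = 0.4, seed = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  with_seed(seed, paste(
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
    collapse = ""))
}

#' Empirical breakpoint position model
#'
#' The mixture the cohort displays: ~83% of TCF3-side breaks fall in a
#' 40 bp hotspot of intron 16, and PBX1-side breaks split ~37% / 51% / 12%
#' between the intron-end cluster, the mid-intron cluster, and the
#' remainder of intron 2. Weights are empirical estimates shipped as
#' configuration, not fitted parameters. `"scaled"` mode shrinks PBX1
#' intron 2 to 20 kb (about 1:11.5, cluster bounds scaled proportionally)
#' so simulations run at desk scale; `"full"` uses real intron lengths.
#'
#' @param mode `"scaled"` (default) or `"full"`.
#' @return list of class `breakpoint_model`.
#' @export
breakpoint_model <- function(mode = c("scaled", "full")) {
  mode <- match.arg(mode)
  full_len <- pbx1_intron2()$length
  if (mode == "full") {
    plen <- full_len
    clusters <- pbx1_cluster_regions()
  } else {
    plen <- 20000L
    sc <- full_len / plen
    full <- pbx1_cluster_regions()
    clusters <- rbind(
      region(as.integer(ceiling(full$start[1] / sc)), plen, "cluster1"),
      region(as.integer(round(full$start[2] / sc)),
             as.integer(round(full$end[2] / sc)), "cluster2"))
  }
  clusters$weight <- c(0.37, 0.51)
  structure(list(
    mode = mode,
    tcf3 = list(length = tcf3_intron16()$length,
                hotspot = region(1163L, 1202L, "hotspot"),
                hotspot_weight = 0.83, background_weight = 0.17),
    pbx1 = list(length = plen, clusters = clusters,
                background_weight = 0.12)),
    class = "breakpoint_model")
}

#' Junction repair model
#'
#' Non-homologous end joining as observed at these junctions: mostly zero
#' microhomology with frequent short non-template insertions, plus rare
#' templated inversions and foreign-sequence captures. The microhomology
#' length distribution and insertion frequency are assumptions (only the
#' qualitative pattern is published); defaults are documented in the
#' package vignette.
#'
#' @param p_mh named probabilities over microhomology lengths 0..k
#'   (default `P(0)=.7, P(1)=.15, P(2)=.1, P(3)=.05`).
#' @param p_insert probability of a non-template insertion given zero
#'   microhomology (default 0.5, "frequent").
#' @param insert_geom_p geometric parameter for insert length minus 1
#'   (default 0.35, mean length ~2.9 bp).
#' @param p_inversion probability of a templated inverted-segment insert
#'   (default 0.02, ~1 of 65 junctions).
#' @param inversion_length inverted segment length (default 788 bp, the
#'   observed case).
#' @param p_foreign probability of a foreign-sequence insert (default 0.02,
#'   ~1 of 49 cases).
#' @param foreign_insert_len range of foreign insert lengths.
#' @param p_reciprocal probability that the reciprocal derivative is emitted
#'   (default 15/49, the fraction of characterized reciprocal junctions).
#' @return list of class `junction_model`.
#' @export
junction_model <- function(p_mh = c(`0` = 0.7, `1` = 0.15, `2` = 0.1,
                                    `3` = 0.05),
                           p_insert = 0.5, insert_geom_p = 0.35,
                           p_inversion = 0.02, inversion_length = 788L,
                           p_foreign = 0.02, foreign_insert_len = c(20L, 200L),
                           p_reciprocal = 15 / 49) {
  stopifnot(abs(sum(p_mh) - 1) < 1e-9, all(p_mh >= 0),
            p_insert >= 0, p_insert <= 1, p_inversion + p_foreign <= 1)
  structure(list(p_mh = p_mh, p_insert = p_insert,
                 insert_geom_p = insert_geom_p, p_inversion = p_inversion,
                 inversion_length = as.integer(inversion_length),
                 p_foreign = p_foreign,
                 foreign_insert_len = as.integer(foreign_insert_len),
                 p_reciprocal = p_reciprocal),
            class = "junction_model")
}

# sample an intron-relative position from a region mixture
.sample_position <- function(len, regions, weights, background_weight) {
  stopifnot(abs(sum(weights) + background_weight - 1) < 1e-9)
  k <- sample.int(length(weights) + 1L, 1L,
                  prob = c(weights, background_weight))
  if (k <= length(weights))
    return(list(pos = sample(regions$start[k]:regions$end[k], 1L),
                component = regions$label[k]))
  inside <- unlist(lapply(seq_len(nrow(regions)), function(i)
    regions$start[i]:regions$end[i]))
  outside <- setdiff(seq_len(len), inside)
  list(pos = sample(outside, 1L), component = "outside")
}

.base_other_than <- function(...) {
  sample(setdiff(c("A", "C", "G", "T"), c(...)), 1L)
}

.char_at <- function(s, i) substr(s, i, i)

# core fusion constructor; consumes the ambient RNG stream
.simulate_fusion_core <- function(tcf3_ref, pbx1_ref, bp_model, j_model,
                                  foreign_db, max_retries = 100L) {
  Lt <- nchar(tcf3_ref); Lp <- nchar(pbx1_ref)
  stopifnot(Lt >= bp_model$tcf3$length, Lp >= bp_model$pbx1$length)

  sx <- .sample_position(bp_model$tcf3$length,
                         bp_model$tcf3$hotspot,
                         bp_model$tcf3$hotspot_weight,
                         bp_model$tcf3$background_weight)
  sy <- .sample_position(bp_model$pbx1$length,
                         bp_model$pbx1$clusters,
                         bp_model$pbx1$clusters$weight,
                         bp_model$pbx1$background_weight)
  x <- sx$pos

  u <- runif(1L)
  type <- if (u < j_model$p_inversion) "inverted-segment"
          else if (u < j_model$p_inversion + j_model$p_foreign) "foreign"
          else "nhej"
  mh <- 0L
  ins <- ""
  if (type == "nhej") {
    mh <- as.integer(names(j_model$p_mh))[
      sample.int(length(j_model$p_mh), 1L, prob = j_model$p_mh)]
    if (mh == 0L && runif(1L) < j_model$p_insert) {
      type <- "non-template"
      k <- rgeom(1L, j_model$insert_geom_p) + 1L
      repeat {
        ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
        ok <- !(nchar(ins) >= 10L &&
                  (grepl(revcomp(ins), tcf3_ref, fixed = TRUE) ||
                   grepl(revcomp(ins), pbx1_ref, fixed = TRUE)))
        if (ok) break
      }
    } else type <- "none"
  } else if (type == "inverted-segment") {
    # templated inserts must keep their source sequence intact, so the
    # donor-flank guard is enforced by resampling, never by mutating bases
    len <- j_model$inversion_length
    for (i in seq_len(max_retries)) {
      y2 <- sample.int(Lp - len, 1L)
      ins <- revcomp(substr(pbx1_ref, y2, y2 + len - 1L))
      if (grepl(ins, tcf3_ref, fixed = TRUE)) next
      if (.char_at(ins, 1L) == .char_at(tcf3_ref, x + 1L)) next
      break
    }
  } else {
    src <- foreign_db[[sample.int(length(foreign_db), 1L)]]
    len <- sample(j_model$foreign_insert_len[1]:j_model$foreign_insert_len[2],
                  1L)
    for (i in seq_len(max_retries)) {
      s0 <- sample.int(nchar(src) - len, 1L)
      ins <- substr(src, s0, s0 + len - 1L)
      if (grepl(revcomp(ins), tcf3_ref, fixed = TRUE) ||
          grepl(revcomp(ins), pbx1_ref, fixed = TRUE) ||
          grepl(ins, tcf3_ref, fixed = TRUE) ||
          grepl(ins, pbx1_ref, fixed = TRUE)) next
      if (.char_at(ins, 1L) == .char_at(tcf3_ref, x + 1L)) next
      break
    }
  }

  # choose the PBX1-side coordinate y subject to exact-recovery guards:
  # junction flanks must not extend the prefix/suffix matches by accident
  y <- NA_integer_
  region_ok <- function(yc) {
    cl <- bp_model$pbx1$clusters
    comp <- "outside"
    for (i in seq_len(nrow(cl)))
      if (yc >= cl$start[i] && yc <= cl$end[i]) comp <- cl$label[i]
    comp == sy$component
  }
  if (mh > 0L && x <= mh) { mh <- 0L; type <- "none" }
  if (mh > 0L) {
    pat <- substr(tcf3_ref, x - mh + 1L, x)
    hits <- gregexpr(pat, pbx1_ref, fixed = TRUE)[[1L]]
    if (hits[1L] != -1L) {
      cand <- hits + mh  # y = position after the matched m-mer
      cand <- cand[cand > mh + 1L & cand <= bp_model$pbx1$length]
      keep <- vapply(cand, function(yc) {
        region_ok(yc) &&
          .char_at(pbx1_ref, yc) != .char_at(tcf3_ref, x + 1L) &&
          .char_at(pbx1_ref, yc - mh - 1L) != .char_at(tcf3_ref, x - mh)
      }, logical(1))
      cand <- cand[keep]
      if (length(cand)) y <- cand[sample.int(length(cand), 1L)]
    }
    if (is.na(y)) { mh <- 0L; type <- "none" }  # no compatible site: clean join
  }
  if (is.na(y)) {
    left <- if (nzchar(ins)) substr(ins, nchar(ins), nchar(ins))
            else .char_at(tcf3_ref, x)
    for (i in seq_len(max_retries)) {
      y <- sy$pos
      if (i > 1L) y <- .sample_position(bp_model$pbx1$length,
                                        bp_model$pbx1$clusters,
                                        bp_model$pbx1$clusters$weight,
                                        bp_model$pbx1$background_weight)$pos
      if (y <= 1L) next
      if (.char_at(pbx1_ref, y - 1L) == left) next
      if (!nzchar(ins) && .char_at(pbx1_ref, y) == .char_at(tcf3_ref, x + 1L))
        next
      break
    }
    if (.char_at(pbx1_ref, y - 1L) == left)
      stop("could not place breakpoint after ", max_retries, " retries",
           call. = FALSE)
  }
  if (type == "non-template" &&
      .char_at(ins, 1L) == .char_at(tcf3_ref, x + 1L)) {
    # fix the first insert base so the donor prefix match stops at x
    substr(ins, 1L, 1L) <- .base_other_than(.char_at(tcf3_ref, x + 1L),
                                            if (nchar(ins) == 1L)
                                              .char_at(pbx1_ref, y - 1L))
  }

  der19 <- paste0(substr(tcf3_ref, 1L, x), ins, substr(pbx1_ref, y, Lp))
  # reciprocal der(1) = PBX1[1..y-1] + TCF3[x+1..end], emitted only when the
  # clean-join guards hold on that junction too (so it round-trips exactly)
  der1 <- NULL
  if (runif(1L) < j_model$p_reciprocal && y > 2L && x < Lt &&
      .char_at(pbx1_ref, y) != .char_at(tcf3_ref, x + 1L) &&
      .char_at(tcf3_ref, x) != .char_at(pbx1_ref, y - 1L)) {
    der1 <- paste0(substr(pbx1_ref, 1L, y - 1L),
                   substr(tcf3_ref, x + 1L, Lt))
  }
  insert_class <- if (!nzchar(ins)) "none"
                  else if (type %in% c("inverted-segment", "foreign")) type
                  else "non-template"
  # record the component of the coordinates actually placed (retries may
  # have moved y out of the originally sampled component)
  cl <- bp_model$pbx1$clusters
  y_comp <- "outside"
  for (i in seq_len(nrow(cl)))
    if (y >= cl$start[i] && y <= cl$end[i]) y_comp <- cl$label[i]
  hs <- bp_model$tcf3$hotspot
  x_comp <- if (x >= hs$start && x <= hs$end) "hotspot" else "outside"
  list(der19 = der19, der1 = der1,
       truth = data.frame(
         tcf3_pos = x, pbx1_pos = y, microhomology = mh,
         insert = ins, insert_class = insert_class,
         tcf3_component = x_comp, pbx1_component = y_comp,
         reciprocal = !is.null(der1)))
}

#' Simulate a t(1;19) derivative chromosome
#'
#' Samples breakpoints from the empirical cluster mixture and a junction
#' event from the NHEJ model, then assembles
#' `der(19) = TCF3[1..x] + insert + PBX1[y..end]`. Junction flanks are
#' constrained so the planted coordinates, microhomology and insert are
#' exactly recoverable by [characterize_junction()] (truth and call agree
#' up to the documented microhomology ambiguity range). The reciprocal
#' der(1) is emitted with the model's configured probability.
#'
#' @param tcf3_ref,pbx1_ref reference intron sequences at least as long as
#'   the model's intron lengths.
#' @param bp_model a [breakpoint_model()].
#' @param j_model a [junction_model()].
#' @param seed optional integer seed.
#' @param foreign_db named character vector of foreign source sequences; by
#'   default one 2 kb sequence is generated from the current stream.
#' @return list with `der19`, `der1` (or `NULL`), `truth` (one-row
#'   data.frame) and `foreign_db`.
#' @export
simulate_fusion <- function(tcf3_ref, pbx1_ref, bp_model = breakpoint_model(),
                            j_model = junction_model(), seed = NULL,
                            foreign_db = NULL) {
  tcf3_ref <- .as_seq(tcf3_ref); pbx1_ref <- .as_seq(pbx1_ref)
  with_seed(seed, {
    if (is.null(foreign_db))
      foreign_db <- c(foreign_like = generate_reference(2000L, gc = 0.45))
    out <- .simulate_fusion_core(tcf3_ref, pbx1_ref, bp_model, j_model,
                                 foreign_db)
    out$foreign_db <- foreign_db
    out
  })
}

#' Simulate a cohort of derivative chromosomes
#'
#' @inheritParams simulate_fusion
#' @param n number of independent fusion events (>= 0).
#' @param fasta_path,truth_path optional output files (FASTA of derivative
#'   sequences; TSV truth table). Outputs are byte-identical for a fixed
#'   seed.
#' @return list with `derivatives` (named character vector; reciprocal
#'   derivatives carry suffix `_der1`) and `truth` (data.frame with one row
#'   per event).
#' @export
simulate_cohort <- function(n, bp_model = breakpoint_model(),
                            j_model = junction_model(), seed = NULL,
                            tcf3_ref = NULL, pbx1_ref = NULL,
                            foreign_db = NULL, fasta_path = NULL,
                            truth_path = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  with_seed(seed, {
    if (is.null(tcf3_ref))
      tcf3_ref <- generate_reference(bp_model$tcf3$length, gc = 0.45)
    if (is.null(pbx1_ref))
      pbx1_ref <- generate_reference(bp_model$pbx1$length, gc = 0.4)
    if (is.null(foreign_db))
      foreign_db <- c(foreign_like = generate_reference(2000L, gc = 0.45))
    seqs <- character(0)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      ev <- .simulate_fusion_core(tcf3_ref, pbx1_ref, bp_model, j_model,
                                  foreign_db)
      id <- sprintf("sim%04d", i)
      seqs[[paste0(id, "_der19")]] <- ev$der19
      if (!is.null(ev$der1)) seqs[[paste0(id, "_der1")]] <- ev$der1
      ev$truth$id <- id
      truth[[i]] <- ev$truth
    }
    truth <- if (n > 0L) do.call(rbind, truth) else
      data.frame(tcf3_pos = integer(), pbx1_pos = integer(),
                 microhomology = integer(), insert = character(),
                 insert_class = character(), tcf3_component = character(),
                 pbx1_component = character(), reciprocal = logical(),
                 id = character())
    if (!is.null(fasta_path)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
    }
    if (!is.null(truth_path))
      write.table(truth, truth_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    list(derivatives = seqs, truth = truth,
         tcf3_ref = tcf3_ref, pbx1_ref = pbx1_ref, foreign_db = foreign_db)
  })
}
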