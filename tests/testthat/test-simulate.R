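test_that("generate_reference is reproducible and respects length/GC", {
  s <- generate_reference(1000, seed = 81)
  expect_identical(nchar(s), 1000L)
  expect_identical(s, generate_reference(1000, seed = 81))
  expect_false(identical(s, generate_reference(1000, seed = 82)))
  # GC within the 99% binomial interval at gc = 0.4, n = 100000
  big <- generate_reference(100000, gc = 0.4, seed = 83)
  gc <- sum(strsplit(big, "")[[1]] %in% c("G", "C"))
  half <- qnorm(0.995) * sqrt(0.4 * 0.6 * 100000)
  expect_lt(abs(gc - 40000), half)
  # the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_reference(10, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("model constructors validate their weights", {
  bm <- breakpoint_model()
  expect_equal(sum(bm$pbx1$clusters$weight) + bm$pbx1$background_weight, 1)
  expect_equal(bm$tcf3$hotspot_weight + bm$tcf3$background_weight, 1)
  expect_identical(breakpoint_model("full")$pbx1$length, 229182L)
  expect_error(junction_model(p_mh = c(`0` = 0.5, `1` = 0.1)), "p_mh")
})

test_that("forced clean joins concatenate exactly at the truth coordinates", {
  jm <- junction_model(p_mh = c(`0` = 1), p_insert = 0,
                       p_inversion = 0, p_foreign = 0)
  bm <- breakpoint_model()
  tref <- generate_reference(bm$tcf3$length, seed = 84)
  pref <- generate_reference(bm$pbx1$length, seed = 85)
  for (seed in 86:90) {
    ev <- simulate_fusion(tref, pref, bm, jm, seed = seed)
    tr <- ev$truth
    expect_identical(ev$der19,
                     paste0(substr(tref, 1, tr$tcf3_pos),
                            substr(pref, tr$pbx1_pos, nchar(pref))))
    expect_identical(tr$microhomology, 0L)
    expect_identical(tr$insert, "")
  }
})

test_that("a forced 788 bp inversion is classified as inverted-segment", {
  jm <- junction_model(p_inversion = 1, p_foreign = 0)
  bm <- breakpoint_model()
  tref <- generate_reference(bm$tcf3$length, seed = 91)
  pref <- generate_reference(bm$pbx1$length, seed = 92)
  ev <- simulate_fusion(tref, pref, bm, jm, seed = 93)
  expect_identical(ev$truth$insert_class, "inverted-segment")
  expect_identical(nchar(ev$truth$insert), 788L)
  j <- characterize_junction(ev$der19, tref, pref)
  expect_identical(j$insert_class, "inverted-segment")
  expect_identical(nchar(j$inserted_seq), 788L)
})

test_that("cohorts are deterministic under a fixed seed, including files", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); t1 <- file.path(d, "a.tsv")
  f2 <- file.path(d, "b.fa"); t2 <- file.path(d, "b.tsv")
  c1 <- simulate_cohort(25, seed = 94, fasta_path = f1, truth_path = t1)
  c2 <- simulate_cohort(25, seed = 94, fasta_path = f2, truth_path = t2)
  expect_identical(c1$derivatives, c2$derivatives)
  expect_identical(c1$truth, c2$truth)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(nrow(simulate_cohort(0, seed = 1)$truth), 0L)
  expect_length(simulate_cohort(0, seed = 1)$derivatives, 0L)
})

test_that("small cohorts round-trip through junction characterization", {
  sim <- simulate_cohort(60, seed = 95)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    j <- characterize_junction(sim$derivatives[[paste0(tr$id, "_der19")]],
                               sim$tcf3_ref, sim$pbx1_ref,
                               foreign_db = sim$foreign_db)
    expect_identical(j$microhomology_len, tr$microhomology)
    expect_identical(j$inserted_seq, tr$insert)
    expect_true(j$donor_range[1] <= tr$tcf3_pos &&
                  tr$tcf3_pos <= j$donor_range[2])
  }
  # reciprocal derivatives anchor the other way around
  recs <- sim$truth[sim$truth$reciprocal, ]
  expect_gt(nrow(recs), 0)
  for (i in seq_len(nrow(recs))) {
    tr <- recs[i, ]
    j <- characterize_junction(sim$derivatives[[paste0(tr$id, "_der1")]],
                               sim$pbx1_ref, sim$tcf3_ref)
    expect_identical(j$donor_break, tr$pbx1_pos - 1L)
    expect_identical(j$microhomology_len, 0L)
  }
})

test_that("full-pipeline round trip: simulate, digest-detect, characterize", {
  # references with planted SphI sites and primer sites flanking the TCF3
  # hotspot so simulated der(19) junctions are detectable by LRI PCR
  bm <- breakpoint_model()
  jm <- junction_model(p_inversion = 0, p_foreign = 0, p_reciprocal = 0)
  set.seed(96)
  tv <- strsplit(generate_reference(bm$tcf3$length, seed = 97), "")[[1]]
  tv[201:206] <- strsplit("GCATGC", "")[[1]]
  fwd <- primer("F", "GATTCGTACCAGTCAGGT")
  rev <- primer("R", "CCATGAGTTGACCTAGGA")
  tv[400:417] <- strsplit(revcomp(rev$sequence), "")[[1]]   # rev pos5 = 417
  tv[600:617] <- strsplit(fwd$sequence, "")[[1]]
  tref <- gsub("GCATGC", "GCATGA",
               paste(tv, collapse = ""), fixed = TRUE)
  tref <- paste0(substr(tref, 1, 200), "GCATGC",
                 substr(tref, 207, nchar(tref)))
  # place the PBX1-side site between cluster 2 and cluster 1 so that
  # cluster-2 junctions fall on a self-ligatable fragment
  pv <- gsub("GCATGC", "GCATGA",
             generate_reference(bm$pbx1$length, seed = 98), fixed = TRUE)
  pref <- paste0(substr(pv, 1, 13599), "GCATGC", substr(pv, 13606, nchar(pv)))
  sphi <- restriction_enzyme("SphI", "GCATGC", 5, 1)

  sim <- simulate_cohort(30, bm, jm, seed = 99, tcf3_ref = tref,
                         pbx1_ref = pref)
  n_det <- 0L
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    der <- sim$derivatives[[paste0(tr$id, "_der19")]]
    det <- breakpoint_detectability(der, tr$tcf3_pos, sphi, fwd, rev,
                                    max_size = 50000)
    if (det$detectable) {
      n_det <- n_det + 1L
      j <- characterize_junction(der, tref, pref)
      expect_true(j$donor_range[1] <= tr$tcf3_pos &&
                    tr$tcf3_pos <= j$donor_range[2])
      expect_identical(j$microhomology_len, tr$microhomology)
    }
  }
  expect_gt(n_det, 0L)
})
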