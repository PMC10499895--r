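# build a template with planted primer sites: fwd on plus at f5, rev (given
# 5'->3') planted as its reverse complement ending at plus-coordinate r5
plant_template <- function(len, fwd, f5, rev, r5, seed = 1) {
  set.seed(seed)
  v <- strsplit(rand_seq(len), "")[[1]]
  v[f5:(f5 + nchar(fwd) - 1)] <- strsplit(fwd, "")[[1]]
  rc <- revcomp(rev)
  v[(r5 - nchar(rc) + 1):r5] <- strsplit(rc, "")[[1]]
  paste(v, collapse = "")
}

FWD <- "GATTCGTACCAGTCAGGT"
REV <- "CCATGAGTTGACCTAGGA"

test_that("find_primer_sites reports both strands and matches a naive scan", {
  set.seed(41)
  host <- rand_seq(500)
  p <- primer("P", "GATTCGTACCAGTCAGGT")
  s <- paste0(substr(host, 1, 100), p$sequence, substr(host, 101, 300),
              revcomp(p$sequence), substr(host, 301, 400),
              p$sequence, substr(host, 401, 500))
  sites <- find_primer_sites(s, p)
  expect_identical(nrow(sites), 3L)
  expect_identical(sites$strand, c("+", "-", "+"))
  expect_identical(sites$start[sites$strand == "+"],
                   oracle_find_all(s, p$sequence))
  expect_identical(sites$start[sites$strand == "-"],
                   oracle_find_all(s, revcomp(p$sequence)))
  # minus-strand pos5 is the site's right edge
  expect_identical(sites$pos5[sites$strand == "-"],
                   sites$end[sites$strand == "-"])
})

test_that("inverse PCR size follows the circular-path definition", {
  f <- primer("F", FWD); r <- primer("R", REV)
  s <- plant_template(100, FWD, 81, REV, 20)
  amp <- inverse_pcr_product(s, f, r)
  expect_identical(amp$size, 40L)       # (100 - 81 + 1) + 20
  expect_true(amp$contains_junction)

  # convergent orientation: ordinary PCR, not an inverse-PCR product
  s2 <- plant_template(100, FWD, 10, REV, 90)
  expect_null(inverse_pcr_product(s2, f, r))
  # absent primer
  expect_null(inverse_pcr_product(rand_seq(100), f, r))
  # double binding is ambiguous
  s3 <- paste0(s, s)
  expect_error(inverse_pcr_product(s3, f, r), "ambiguous")
})

test_that("inverse PCR size is invariant under rotation of the circle", {
  f <- primer("F", FWD); r <- primer("R", REV)
  s <- plant_template(120, FWD, 90, REV, 30, seed = 5)
  ref <- inverse_pcr_product(s, f, r)$size
  for (k in c(10, 45, 77, 113)) {
    rot <- paste0(substr(s, k + 1, 120), substr(s, 1, k))
    sites <- find_primer_sites(rot, f)
    amp <- if (sites$strand[1] == "+") inverse_pcr_product(rot, f, r)
           else inverse_pcr_product(rot, r, f)
    # rotation may put the pair in convergent orientation on the new
    # linearization; the product over the junction keeps the same size
    # whenever it exists in inverse orientation
    if (!is.null(amp)) expect_identical(amp$size, ref)
  }
})

test_that("fragment rows must be self-ligatable", {
  f <- primer("F", FWD); r <- primer("R", REV)
  s <- plant_template(100, FWD, 81, REV, 20)
  frag <- digest(s, restriction_enzyme("SphI", "GCATGC", 5, 1))[1, ]
  expect_error(inverse_pcr_product(frag, f, r), "self-ligate")
})

test_that("control bands on a planted mini reference are hand-computable", {
  sphi <- restriction_enzyme("SphI", "GCATGC", 5, 1)
  f <- primer("F", FWD); r <- primer("R", REV)
  # layout: SphI at 101 (cut after 105), rev r5 = 200, fwd f5 = 400,
  # SphI at 601 (cut after 605); fragment = [106, 605], L = 500
  set.seed(42)
  v <- strsplit(rand_seq(800), "")[[1]]
  v[101:106] <- strsplit("GCATGC", "")[[1]]
  v[601:606] <- strsplit("GCATGC", "")[[1]]
  rc <- revcomp(REV)
  v[(200 - nchar(rc) + 1):200] <- strsplit(rc, "")[[1]]
  v[400:(400 + nchar(FWD) - 1)] <- strsplit(FWD, "")[[1]]
  s <- paste(v, collapse = "")
  # hand: local f5 = 400-105 = 295, local r5 = 200-105 = 95,
  # size = 500 - 295 + 1 + 95 = 301
  bands <- control_band_sizes(s, sphi, list(list(f, r)))
  expect_identical(unname(bands["F/R"]), 301)
  # absent primer reported NA with reason
  other <- primer("Q", "ACCAGTTGGCATCCAGTT")
  bands2 <- control_band_sizes(s, sphi, list(list(f, other)))
  expect_true(is.na(bands2["F/Q"]))
  expect_match(attr(bands2, "reasons")["F/Q"], "absent")
})

test_that("synthetic region reproduces all six published control bands", {
  reg <- synthetic_tcf3_region()
  enz <- lri_enzymes()
  pairs <- lri_control_pairs()
  got <- c(control_band_sizes(reg, enz$BamHI, pairs$BamHI),
           control_band_sizes(reg, enz$SphI, pairs$SphI),
           control_band_sizes(reg, enz$TaqI, pairs$TaqI))
  expect_identical(unname(got),
                   c(3308, 2131, 5026, 3849, 7567, 6390))
})

test_that("screen_enzymes applies all suitability criteria", {
  db <- c(lri_enzymes(), list(
    EcoRV = restriction_enzyme("EcoRV", "GATATC", 3, 3),
    BstEII = restriction_enzyme("BstEII", "GGTNACC", 1, 6),
    NotI = restriction_enzyme("NotI", "GCGGCCGC", 2, 6)))
  reg <- synthetic_tcf3_region()
  res <- screen_enzymes(db, reg, region(5000, 8000))
  expect_true(all(res$pass[res$name %in% c("SphI", "BamHI", "TaqI")]))
  expect_false(res$pass[res$name == "EcoRV"])   # blunt
  expect_false(res$sticky[res$name == "EcoRV"])
  expect_false(res$pass[res$name == "BstEII"])  # degenerate
  expect_false(res$pass[res$name == "NotI"])    # 8-cutter
  # passing enzymes ranked by fragment length
  pl <- res$fragment_len[res$pass]
  expect_true(all(diff(pl) >= 0))
})

test_that("breakpoint detectability needs junction and primers co-fragment", {
  sphi <- restriction_enzyme("SphI", "GCATGC", 5, 1)
  f <- primer("F", FWD); r <- primer("R", REV)
  set.seed(43)
  v <- strsplit(rand_seq(3000), "")[[1]]
  v[101:106] <- strsplit("GCATGC", "")[[1]]
  rc <- revcomp(REV)
  v[283:300] <- strsplit(rc, "")[[1]]
  v[500:517] <- strsplit(FWD, "")[[1]]
  v[2001:2006] <- strsplit("GCATGC", "")[[1]]
  s <- paste(v, collapse = "")

  # junction on the primer fragment, product small enough -> detectable;
  # fragment [106+1=106.. ] cut after 105 and 2005: L = 1900
  # size = 1900 - (500-105) + 1 + (300-105) = 1701
  det <- breakpoint_detectability(s, 1000, sphi, f, r, max_size = 10000)
  expect_true(det$detectable)
  expect_identical(det$size, 1701L)

  # enzyme site between primer region and junction: junction off-fragment
  det2 <- breakpoint_detectability(s, 2500, sphi, f, r)
  expect_false(det2$detectable)
  expect_match(det2$reason, "junction not on primer fragment")

  # junction destroying the nearer 3' site: fragment extends into partner
  # DNA (next site far away) and the junction becomes detectable
  v2 <- v
  v2[2001:2006] <- strsplit("AAAAAA", "")[[1]]   # fusion destroyed the site
  v2[2801:2806] <- strsplit("GCATGC", "")[[1]]   # next site in partner DNA
  s2 <- paste(v2, collapse = "")
  det3 <- breakpoint_detectability(s2, 2500, sphi, f, r)
  expect_true(det3$detectable)

  # product size cap
  det4 <- breakpoint_detectability(s, 1000, sphi, f, r, max_size = 1000)
  expect_false(det4$detectable)
  expect_match(det4$reason, "exceeds")
})

test_that("multiplex products bracket the junction and respect max_size", {
  f <- primer("F", FWD)
  r1 <- primer("R1", REV)
  r2 <- primer("R2", "TTCAGGCCATAGACCGTA")
  set.seed(44)
  v <- strsplit(rand_seq(2000), "")[[1]]
  v[100:117] <- strsplit(FWD, "")[[1]]
  v[(600 - 17):600] <- strsplit(revcomp(REV), "")[[1]]
  v[(1500 - 17):1500] <- strsplit(revcomp(r2$sequence), "")[[1]]
  s <- paste(v, collapse = "")
  res <- multiplex_products(s, f, list(r1, r2), max_size = 10000)
  expect_identical(res$size, c(501L, 1401L))  # r5 - f5 + 1, hand-computed
  # junction between the two panel sites: only the distal product brackets
  res2 <- multiplex_products(s, f, list(r1, r2), junction_pos = 800)
  expect_identical(res2$reverse, "R2")
  # junction outside the covered region: empty
  res3 <- multiplex_products(s, f, list(r1, r2), junction_pos = 1600)
  expect_identical(nrow(res3), 0L)
  # max_size excludes the distal product
  res4 <- multiplex_products(s, f, list(r1, r2), max_size = 600)
  expect_identical(res4$reverse, "R1")
})
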