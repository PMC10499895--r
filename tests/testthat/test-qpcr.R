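test_that("a constructed exact line is fitted exactly", {
  pts <- data.frame(log10_concentration = c(0, -1, -2, -3, -4),
                    ct = c(10.000, 13.334, 16.668, 20.002, 23.336))
  fit <- fit_standard_curve(pts)
  expect_equal(fit$slope, -3.334, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 10.0, tolerance = 1e-9)
  expect_equal(fit$efficiency, 10^(1 / 3.334) - 1, tolerance = 1e-12)
})

test_that("least squares matches the normal-equations oracle to 1e-9", {
  set.seed(61)
  for (i in 1:10) {
    x <- round(runif(20, -5, 0), 3)
    y <- 20 - 3.3 * x + rnorm(20, sd = 0.4)
    fit <- fit_standard_curve(data.frame(log10_concentration = x, ct = y))
    o <- oracle_ols(x, y)
    expect_equal(fit$slope, unname(o["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-9)
  }
})

test_that("degenerate standard curves follow the contract", {
  two <- data.frame(log10_concentration = c(0, -2), ct = c(10, 17))
  fit <- fit_standard_curve(two)
  expect_equal(fit$slope, -3.5)
  expect_equal(fit$r_squared, 1.0)
  expect_error(fit_standard_curve(
    data.frame(log10_concentration = c(-1, -1, -1), ct = c(1, 2, 3))),
    "distinct")
  # a 4-point curve (one missing Ct) is accepted
  four <- data.frame(log10_concentration = 0:-4,
                     ct = c(12, 15.4, 18.9, 22.3, NA))
  expect_identical(fit_standard_curve(four)$n, 4L)
})

test_that("efficiency_from_slope reproduces printed values and is monotone", {
  expect_equal(round(efficiency_from_slope(-3.418), 3), 0.961)
  expect_equal(round(efficiency_from_slope(-3.334), 3), 0.995)
  expect_equal(round(efficiency_from_slope(-3.039), 3), 1.133)
  expect_equal(efficiency_from_slope(-1 / log10(2)), 1.0, tolerance = 1e-12)
  expect_error(efficiency_from_slope(0.5), "negative")
  expect_error(efficiency_from_slope(0), "negative")
  s <- seq(-5, -2, by = 0.1)
  expect_true(all(diff(efficiency_from_slope(s)) > 0))
})

test_that("successive delta Ct reproduces a printed dilution series", {
  # Cts constructed to carry the printed deltas 3.52/3.28/3.60/3.19
  expect_equal(successive_delta_ct(c(20.00, 23.52, 26.80, 30.40, 33.59)),
               c(3.52, 3.28, 3.60, 3.19))
  expect_equal(successive_delta_ct(c(5, 5)), 0)
  expect_error(successive_delta_ct(21), "at least 2")
  set.seed(62)
  v <- runif(8, 10, 35)
  expect_equal(successive_delta_ct(v), v[-1] - v[-8])
})

test_that("every packaged curve's printed efficiency matches its slope", {
  tab <- qpcr_reference_curves()
  expect_identical(nrow(tab), 15L)
  recomputed <- round(efficiency_from_slope(tab$slope), 3)
  # one printed efficiency (patient 7979) is off by 0.001 from its own
  # printed slope; see the acceptance suite and package vignette
  expect_true(all(abs(recomputed - tab$efficiency) <= 0.001))
  expect_identical(sum(abs(recomputed - tab$efficiency) > 0.0005), 1L)
  # the one 4-point curve has a missing delta45
  expect_identical(sum(is.na(tab$delta45)), 1L)
  expect_identical(tab$patient[is.na(tab$delta45)], "ML13772")
})

test_that("simulated curves recover the slope within 3 standard errors", {
  set.seed(63)
  hits <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    x <- rep(0:-4, each = 2)
    y <- 12 - 3.32 * x + rnorm(length(x), sd = 0.25)
    fit <- lm(y ~ x)
    se <- summary(fit)$coefficients["x", "Std. Error"]
    if (abs(coef(fit)[["x"]] - (-3.32)) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("melting temperatures match the published rules and a frozen NN oracle", {
  expect_identical(melting_temperature("ACGT", method = "wallace"), 12)
  expect_identical(melting_temperature("AATT", method = "wallace"), 8)
  expect_error(melting_temperature("ACGN", method = "wallace"), "non-ACGT")
  # frozen values from an independent nearest-neighbor implementation
  # (same unified parameter set, 250 nM primer, 50 mM Na+)
  frozen <- c(CAGGCAGACTTTCCAAGTACCTT = 58.203959,
              CTCCCTGACCTGTCTCGGCCTCCCGACT = 70.374148,
              ACGTTGCAATGCCGTA = 53.445674,
              AGCGTAGCTAGCTAGGATCGAT = 58.259541)
  for (s in names(frozen))
    expect_equal(melting_temperature(s), unname(frozen[s]), tolerance = 1e-4)
})

test_that("reverse primer design spans the constraints", {
  comp <- qpcr_assay_components()
  don <- paste0(generate_reference(200, seed = 71), comp$forward$sequence,
                "TT", comp$probe$sequence, generate_reference(40, seed = 72))
  acc <- generate_reference(500, seed = 73)
  fus <- paste0(don, substr(acc, 200, 500))
  cand <- design_reverse_primer(fus, nchar(don), don, acc)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$length >= 18 & cand$length <= 30))
  expect_true(all(cand$tm >= 58 & cand$tm <= 62))
  expect_true(all(cand$amplicon_len <= 300))
  expect_true(all(cand$start > nchar(don)))   # 3' of the junction

  # junction 10 bp from the sequence end: no room for any candidate
  fus2 <- paste0(don, substr(acc, 200, 209))
  cand2 <- design_reverse_primer(fus2, nchar(don), don, acc)
  expect_identical(nrow(cand2), 0L)
  expect_gt(attr(cand2, "failure_tally")["no_room"], 0)

  # planting the best candidate's site downstream of a forward-primer site
  # in the donor reference makes the assay amplify normal DNA -> rejected
  site <- substr(fus, cand$start[1], cand$end[1])
  don_dup <- paste0(don, generate_reference(20, seed = 74), site)
  cand3 <- design_reverse_primer(fus, nchar(don), don_dup, acc)
  expect_false(cand$sequence[1] %in% cand3$sequence)
  expect_true(nrow(cand3) < nrow(cand))

  # forward primer missing entirely
  expect_error(design_reverse_primer(substr(fus, 250, nchar(fus)),
                                     nchar(don) - 249, don, acc),
               "forward primer")
})
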