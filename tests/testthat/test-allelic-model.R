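test_that("expected observed VAF reproduces hand-computed admixture values", {
  # pure tumor: observed fraction equals the copy fraction
  expect_equal(expected_observed_vaf(1, 1, 2, "germline_het"), 2 / 3)
  # half tumor, germline het, cn (1,2): (0.5 + 1.0)/(1.0 + 1.5)
  expect_equal(expected_observed_vaf(0.5, 1, 2, "germline_het"), 0.6)
  # somatic locus: normal cells contribute two REF copies
  expect_equal(expected_observed_vaf(0.5, 1, 2, "somatic"), 0.4)
})

test_that("deconvolution reproduces hand evaluation of the printed equations", {
  # pure tumor: correction is the identity
  d <- deconvolve_counts(40, 60, 1, 2, 3, "germline_het")
  expect_equal(d$ref_tumor, 40)
  expect_equal(d$alt_tumor, 60)
  expect_equal(d$vaf_tumor, 0.6)
  # germline: ref 40*0.5/1.0 = 20, alt 60*1.0/1.5 = 40
  d <- deconvolve_counts(40, 60, 0.5, 1, 2, "germline_het")
  expect_equal(d$ref_tumor, 20)
  expect_equal(d$alt_tumor, 40)
  expect_equal(d$vaf_tumor, 2 / 3)
  # somatic: ref 60*0.5/1.5 = 20, alt kept in full
  d <- deconvolve_counts(60, 40, 0.5, 1, 2, "somatic")
  expect_equal(d$ref_tumor, 20)
  expect_equal(d$alt_tumor, 40)
  expect_equal(d$vaf_tumor, 2 / 3)
  # LOH of the wild-type allele: all REF reads are normal contamination
  d <- deconvolve_counts(10, 90, 0.8, 0, 1, "somatic")
  expect_equal(d$ref_tumor, 0)
  expect_equal(d$vaf_tumor, 1)
})

test_that("feeding expectation-valued counts back recovers the copy fraction", {
  depth <- 100
  for (p in seq(0.05, 1, by = 0.05)) {
    for (cn_ref in 0:3) {
      for (cn_alt in 0:3) {
        if (cn_ref + cn_alt == 0) next
        for (cls in c("germline_het", "somatic")) {
          v <- expected_observed_vaf(p, cn_ref, cn_alt, cls)
          d <- deconvolve_counts(depth * (1 - v), depth * v, p,
                                 cn_ref, cn_alt, cls)
          expect_equal(d$vaf_tumor, cn_alt / (cn_ref + cn_alt),
                       tolerance = 1e-12,
                       label = sprintf("p=%g cn=(%d,%d) %s",
                                       p, cn_ref, cn_alt, cls))
        }
      }
    }
  }
})

test_that("limit identities hold: pure tumor, balanced germline, REF loss", {
  set.seed(11)
  for (i in 1:50) {
    ref <- sample(0:200, 1); alt <- sample(1:200, 1)
    obs <- alt / (ref + alt)
    cn_ref <- runif(1, 0, 3); cn_alt <- runif(1, 0.1, 3)
    # p = 1: observed VAF for both classes, any cn
    for (cls in c("germline_het", "somatic")) {
      expect_equal(
        deconvolve_counts(ref, alt, 1, cn_ref, cn_alt, cls)$vaf_tumor, obs)
    }
    # balanced diploid germline: observed VAF for any purity
    p <- runif(1, 0.05, 1)
    expect_equal(
      deconvolve_counts(ref, alt, p, 1, 1, "germline_het")$vaf_tumor, obs)
  }
})

test_that("vaf_tumor is bounded, never exceeds observed counts, and is monotone in the ALT fraction", {
  set.seed(23)
  for (i in 1:200) {
    p <- runif(1, 0.05, 1)
    cn_ref <- sample(0:3, 1); cn_alt <- sample(0:3, 1)
    if (cn_ref + cn_alt == 0) cn_alt <- 1
    cls <- sample(c("germline_het", "somatic"), 1)
    depth <- 100
    alts <- sort(sample(0:depth, 5))
    suppressWarnings(
      d <- deconvolve_counts(depth - alts, alts, p, cn_ref, cn_alt, cls))
    expect_true(all(d$ref_tumor <= depth - alts + 1e-12))
    expect_true(all(d$alt_tumor <= alts + 1e-12))
    ok <- !is.na(d$vaf_tumor)
    expect_true(all(d$vaf_tumor[ok] >= 0 & d$vaf_tumor[ok] <= 1))
    # strict monotonicity wherever the deconvoluted VAF is defined and
    # not pinned at a bound by cn_alt = 0 or cn_ref = 0
    if (cn_alt > 0 && cn_ref > 0) {
      expect_true(all(diff(d$vaf_tumor) > 0))
    }
  }
})

test_that("deconvolution agrees with the read-origin enumeration oracle", {
  set.seed(37)
  for (i in 1:1000) {
    p <- runif(1, 0.1, 0.9)
    cn_ref <- sample(0:2, 1)
    cn_alt <- sample(1:3, 1)
    cls <- sample(c("germline_het", "somatic"), 1)
    ref <- sample(0:500, 1); alt <- sample(1:500, 1)
    got <- deconvolve_counts(ref, alt, p, cn_ref, cn_alt, cls)
    want <- oracle_deconvolve(ref, alt, p, cn_ref, cn_alt, cls)
    expect_equal(got$ref_tumor, want$ref_tumor, tolerance = 1e-9)
    expect_equal(got$alt_tumor, want$alt_tumor, tolerance = 1e-9)
    expect_equal(got$vaf_tumor, want$vaf_tumor, tolerance = 1e-9)
  }
})

test_that("ASE fold matches hand-computed odds ratios", {
  # RNA odds equal to copy odds: no allele-specific expression
  expect_equal(ase_fold(60, 40, 0.5, 1, 2, "somatic")$fold, 1)
  # somatic over-expression: ref_tumor 20*0.5/1.5, odds 12, copy odds 2
  r <- ase_fold(20, 80, 0.5, 1, 2, "somatic")
  expect_equal(r$fold, 6)
  expect_equal(r$dna_copy_fraction, 2 / 3)
  # repression of the ALT-bearing (germline-mutant) copy
  expect_equal(ase_fold(80, 20, 0.5, 1, 1, "germline_het")$fold, 0.25)
})

test_that("ASE fold errors on undefined configurations and warns when ineligible", {
  expect_error(ase_fold(10, 90, 0.8, 0, 1, "somatic"), "cn_ref = 0")
  expect_error(ase_fold(0, 50, 1, 1, 1, "somatic"), "REF")
  expect_warning(ase_fold(50, 50, 0.5, 1, 1, "germline_het",
                          eligible = FALSE),
                 "conditions not met")
})

test_that("RNA-applicability conditions combine as a conjunction", {
  expect_true(ase_eligibility(FALSE, TRUE))
  expect_false(ase_eligibility(TRUE, TRUE))
  expect_false(ase_eligibility(FALSE, FALSE))
})

test_that("unbiased RNA counts give a median ASE fold near 1", {
  set.seed(41)
  n <- 500; depth <- 2000
  folds <- numeric(n)
  for (i in seq_len(n)) {
    p <- runif(1, 0.3, 0.9)
    cn <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))[sample(4, 1), ]
    cls <- sample(c("germline_het", "somatic"), 1)
    v <- expected_observed_vaf(p, cn[1], cn[2], cls)
    alt <- rbinom(1, depth, v)
    folds[i] <- ase_fold(depth - alt, alt, p, cn[1], cn[2], cls)$fold
  }
  expect_gt(median(folds), 0.9)
  expect_lt(median(folds), 1.1)
})

test_that("invalid purity, copy number and depth are rejected", {
  expect_error(expected_observed_vaf(0, 1, 1, "germline_het"), "purity")
  expect_error(expected_observed_vaf(1.2, 1, 1, "germline_het"), "purity")
  expect_error(deconvolve_counts(10, 10, 0.5, 0, 0, "germline_het"),
               "positive")
  expect_error(deconvolve_counts(0, 0, 0.5, 1, 1, "germline_het"),
               "depth-zero")
  expect_error(deconvolve_counts(10, 10, 0.5, 1, 1, "intronic"),
               "locus_class")
  expect_warning(deconvolve_counts(50, 50, 0.5, 2, 0, "somatic"),
                 "segmentation may be wrong")
})

test_that("bootstrap interval brackets the estimate and is seed-stable", {
  ci1 <- vaf_confint(300, 700, 0.6, 1, 2, "germline_het", n_boot = 500,
                     seed = 5)
  ci2 <- vaf_confint(300, 700, 0.6, 1, 2, "germline_het", n_boot = 500,
                     seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1["lower"], ci1["estimate"])
  expect_gt(ci1["upper"], ci1["estimate"])
  expect_lt(ci1["upper"] - ci1["lower"], 0.2)
})
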