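# two-exon toy gene used throughout: coding 101-160 and 201-280 on chrT
toy_gene <- function() gene_model("TSG1", "chrT", c(101L, 201L), c(160L, 280L))

test_that("effect qualification follows the nonsynonymous/frameshift coding rule", {
  g <- toy_gene()
  expect_true(classify_variant_effect("chrT", 120, "C", "T", "nonsense", g))
  expect_true(classify_variant_effect("chrT", 120, "C", "T", "missense", g))
  expect_false(classify_variant_effect("chrT", 120, "C", "T", "synonymous", g))
  expect_false(classify_variant_effect("chrT", 120, "CTG", "C",
                                       "inframe_indel", g))
  # outside coding intervals
  expect_false(classify_variant_effect("chrT", 180, "C", "T", "nonsense", g))
  expect_false(classify_variant_effect("chr2", 120, "C", "T", "nonsense", g))
  # frameshift deletion straddling the left exon boundary: spans 95..104,
  # overlaps coding 101-160 by four bases
  expect_true(classify_variant_effect("chrT", 95, "ACGTACGTAC", "A",
                                      "frameshift_indel", g))
  # same deletion ending one base short of the exon
  expect_false(classify_variant_effect("chrT", 95, "ACGTA", "A",
                                       "frameshift_indel", g))
  expect_error(classify_variant_effect("chrT", 120, "C", "T",
                                       "splice_site", g),
               "unknown effect")
})

mkvar <- function(id, pos, origin, effect, ref = "C", alt = "T") {
  data.frame(variant_id = id, chrom = "chrT", pos = pos, ref = ref,
             alt = alt, origin = origin, effect = effect,
             stringsAsFactors = FALSE)
}

test_that("two-hit taxonomy assigns each inactivation pattern correctly", {
  g <- toy_gene()
  # germline nonsense + somatic frameshift: classical two-hit
  v <- rbind(mkvar("v1", 210, "germline", "nonsense"),
             mkvar("v2", 110, "somatic", "frameshift_indel", ref = "CA",
                   alt = "C"))
  call <- classify_sample_genotype(v, g, cn_ref_tumor = 1, cn_alt_tumor = 2)
  expect_equal(call$status, "two_hit")
  expect_true(call$mut_flag)
  # somatic frameshift with complete wild-type loss
  v <- mkvar("v1", 110, "somatic", "frameshift_indel", ref = "CA", alt = "C")
  call <- classify_sample_genotype(v, g, cn_ref_tumor = 0, cn_alt_tumor = 1)
  expect_equal(call$status, "somatic_only_LOH")
  expect_true(call$mut_flag)
  # same variant, wild-type copy retained
  call <- classify_sample_genotype(v, g, cn_ref_tumor = 1, cn_alt_tumor = 1)
  expect_equal(call$status, "somatic_only_no_LOH")
  # and with no copy-number estimate at all
  call <- classify_sample_genotype(v, g)
  expect_equal(call$status, "somatic_only_no_LOH")
  expect_match(call$notes, "LOH not assessable")
  # germline truncating mutation only
  v <- mkvar("v1", 210, "germline", "frameshift_indel", ref = "CA", alt = "C")
  call <- classify_sample_genotype(v, g, cn_ref_tumor = 1, cn_alt_tumor = 1)
  expect_equal(call$status, "germline_only")
  expect_true(call$mut_flag)
  # no qualifying variant at all
  call <- classify_sample_genotype(mkvar("v1", 120, "somatic", "synonymous"),
                                   g, cn_ref_tumor = 1, cn_alt_tumor = 1)
  expect_equal(call$status, "wild_type")
  expect_false(call$mut_flag)
  expect_equal(call$evidence, "")
})

test_that("near-zero copy number yields a possible-LOH note, not a status change", {
  g <- toy_gene()
  v <- mkvar("v1", 110, "somatic", "nonsense")
  call <- classify_sample_genotype(v, g, cn_ref_tumor = 0.1,
                                   cn_alt_tumor = 1.4)
  expect_equal(call$status, "somatic_only_no_LOH")
  expect_match(call$notes, "possible LOH")
})

test_that("mut_flag is monotone and classification is order-invariant", {
  g <- toy_gene()
  set.seed(19)
  pool <- rbind(
    mkvar("q1", 130, "germline", "nonsense"),
    mkvar("q2", 240, "somatic", "frameshift_indel", ref = "CA", alt = "C"),
    mkvar("n1", 150, "somatic", "synonymous"),
    mkvar("n2", 180, "germline", "nonsense"),  # intronic position
    mkvar("q3", 250, "somatic", "missense"))
  for (i in 1:20) {
    take <- sample(nrow(pool), sample(nrow(pool), 1))
    v <- pool[take, , drop = FALSE]
    base <- classify_sample_genotype(v, g, 1, 1)
    # permutation invariance (up to evidence ordering)
    perm <- classify_sample_genotype(v[sample(nrow(v)), , drop = FALSE],
                                     g, 1, 1)
    expect_equal(perm$status, base$status)
    expect_equal(perm$mut_flag, base$mut_flag)
    # adding a qualifying variant never clears the mutant flag
    more <- rbind(v, mkvar("extra", 135, "somatic", "nonsense"))
    expect_true(classify_sample_genotype(more, g, 1, 1)$mut_flag)
    # every sample lands in exactly one status
    expect_true(base$status %in% c("wild_type", "germline_only",
                                   "somatic_only_LOH", "two_hit",
                                   "somatic_only_no_LOH"))
  }
})

test_that("truncating variants are marked in the evidence string", {
  g <- toy_gene()
  v <- rbind(mkvar("v1", 210, "germline", "nonsense"),
             mkvar("v2", 110, "somatic", "missense"))
  call <- classify_sample_genotype(v, g, 1, 2)
  expect_match(call$evidence, "germline:v1\\*")
  expect_match(call$evidence, "somatic:v2($|,)")  # missense: no mark
})
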