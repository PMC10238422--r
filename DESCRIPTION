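Package: intravaf
Title: Tumor-Purity-Aware Allelic Imbalance, Allele-Specific Expression,
    and APOBEC Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolutes observed DNA and RNA allelic read counts from
    admixed tumor specimens into tumor-cell-intrinsic variant allele
    frequencies using tumor purity and allele-specific copy number,
    quantifies allele-specific expression of two-hit tumor-suppressor
    genes from paired DNA/RNA allelic counts, classifies samples by
    biallelic-inactivation pattern (two-hit, somatic with loss of
    heterozygosity, germline-only), and computes the APOBEC tCw
    trinucleotide enrichment score with a one-sided Fisher exact test.
    Includes a seeded synthetic-cohort generator with ground-truth files
    for recovery testing, and an end-to-end pipeline over VCF, segment,
    and allelic-count inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
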