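# intravaf

Tumor-purity-aware allelic imbalance analysis for bulk tumor sequencing:
intratumor VAF deconvolution, allele-specific expression of two-hit
tumor-suppressor genes, biallelic-inactivation classification, and the
APOBEC tCw enrichment statistic — with a seeded synthetic-cohort generator
for ground-truth validation.

## The problem

A bulk tumor specimen mixes tumor cells (fraction *p*, the purity) with
normal cells, so the observed variant allele frequency (VAF) at any locus
confounds tumor copy number, normal contamination, and purity. Given *p*
and the tumor's allele-specific copy number (CN<sup>REF</sup><sub>tumor</sub>,
CN<sup>ALT</sup><sub>tumor</sub>, from callers such as Sequenza or PureCN),
the observed REF/ALT read counts can be deconvoluted into tumor-only
counts. At a germline-heterozygous locus:

    REF_tumor = REF · p·CN_ref / ((1−p) + p·CN_ref)
    ALT_tumor = ALT · p·CN_alt / ((1−p) + p·CN_alt)

At a somatic locus both normal copies read as REF, and every ALT read is
tumor-derived:

    REF_tumor = REF · p·CN_ref / (2(1−p) + p·CN_ref)
    ALT_tumor = ALT

and the intratumor VAF is `ALT_tumor / (REF_tumor + ALT_tumor)`. Applied
to RNA allelic counts (valid when the gene is not differentially expressed
in the cohort and transcription is copy-proportional), the corrected RNA
allelic odds divided by the DNA copy-number odds gives an allele-specific
expression (ASE) fold: 1 under copy-proportional expression, > 1 when the
ALT-bearing copies are over-expressed.

The package targets analysts of small tumor cohorts with paired
tumor/normal DNA (and optionally tumor RNA) allelic counts who need
tumor-cell-intrinsic quantities: who has biallelic inactivation of a
tumor-suppressor gene (two-hit, somatic + LOH, germline-only), which gene
copy is expressed, and whether the somatic C>T spectrum is enriched at
APOBEC TCW motifs.

## Worked example

```r
library(intravaf)

# Observed tumor-DNA counts 40 REF / 60 ALT at a germline-het locus,
# purity 0.5, tumor carries 1 REF-bearing and 2 ALT-bearing copies:
deconvolve_counts(40, 60, purity = 0.5, cn_ref = 1, cn_alt = 2,
                  locus_class = "germline_het")
#>   ref_tumor alt_tumor vaf_tumor
#> 1        20        40 0.6666667

# The observed VAF 0.6 deconvolutes to 2/3 — exactly the tumor copy
# fraction 2/(1+2): this locus is allelically imbalanced by copy number
# alone.

# Tumor-RNA counts 20 REF / 80 ALT at a somatic locus with the same CN:
ase_fold(20, 80, purity = 0.5, cn_ref = 1, cn_alt = 2,
         locus_class = "somatic")
#> ASE fold: 6.000 (RNA vaf_tumor 0.923 vs DNA copy fraction 0.667)

# The mutant copies produce 6x more transcript than their copy number
# explains: allele-specific over-expression of the somatically mutated
# allele.
```

The `analysis/` scripts run the same machinery as a cohort-scale workflow
on a simulated 10-sample cohort (run them in order from the repository
root):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_deconvolve_vaf.R
Rscript analysis/03_allele_specific_expression.R
Rscript analysis/04_two_hit_classification.R
Rscript analysis/05_apobec_enrichment.R
```

which report, among other things:

```
Germline-het loci within 0.02 of the true copy fraction: 100.0% (n = 5000)
Median |error|: 0.0029 after correction vs 0.0078 for the raw observed VAF
ASE folds at somatic hit loci ... Range 4.00 - 4.04, median 4.03
Scenario recovery: 10/10 correct (100%)
Median score 2.94; all p < 0.05: TRUE
Null calibration: median score 0.995 over 500 replicates
```

i.e. the deconvolution recovers true tumor copy fractions at depth 10,000,
the ASE estimator recovers the configured expression factor (4) at somatic
hit loci, all inactivation scenarios are classified correctly, and the
APOBEC score separates an enriched spectrum (60% of C>T at TCW) from a
well-calibrated null. Tables land under `results/`, raw simulated cohorts
under `scratch/`.

## Package layout

- `R/` — the implementation: admixture model and deconvolution
  (`allelic-model.R`), two-hit classifier (`genotype.R`), trinucleotide
  matrix and APOBEC statistic (`trinuc.R`), synthetic-cohort generator
  (`simulate.R`), cohort pipeline and file formats (`pipeline.R`).
- `analysis/` — numbered workflow drivers over the package.
- `vignettes/allelic-imbalance.Rmd` — the model, its assumptions, design
  choices, and limitations.
- `tests/testthat/` — unit, property and acceptance tests, including
  independent brute-force oracles for the deconvolution, the Fisher test,
  and the context counting.
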