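---
title: "Purity-aware allelic imbalance: model, estimators, and design choices"
author: "intravaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware allelic imbalance: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A bulk tumor specimen is a mixture: a fraction $p$ of its cells are tumor
cells, the rest are admixed normal cells. At any variant locus the
sequencer reports REF and ALT read counts pooled over both populations, so
the observed variant allele frequency (VAF) confounds three things — the
tumor's allele-specific copy number, the normal cells' diploid
contribution, and the purity. For questions about the tumor itself (is the
wild-type allele lost? is one gene copy silenced?) one wants the
*intratumor VAF*: the VAF that would be observed if every cell in the
specimen were a tumor cell.

`intravaf` implements that deconvolution, applies it to RNA allelic counts
to quantify allele-specific expression (ASE) of a two-hit tumor-suppressor
gene, classifies samples by biallelic-inactivation pattern, and computes
the APOBEC tCw trinucleotide enrichment statistic. Because desk-scale
validation cannot use patient sequencing data, the package carries a
first-class synthetic-cohort generator whose forward model is exactly the
admixture model the estimators invert, with ground-truth files for
recovery testing.

## The admixture model and its inverse

Let $CN^{REF}_{tumor}$ and $CN^{ALT}_{tumor}$ be the copy numbers of the
REF-bearing and ALT-bearing copies in tumor cells (non-integer subclonal
averages are accepted; all formulas are continuous in them). Normal cells
are diploid: at a germline-heterozygous locus they carry one REF and one
ALT copy; at a somatic locus they carry no ALT copy, and — the one subtle
term — *both* of their copies produce REF reads, including the copy on the
haplotype that is somatically mutated in tumor cells.

Read counts are apportioned by copy mass. The expected observed ALT
fraction (`expected_observed_vaf()`, the simulator's rate) is

$$\mathbb{E}[\mathrm{VAF}_{obs}]
 = \frac{(1-p)\,CN^{ALT}_{normal} + p\,CN^{ALT}_{tumor}}
        {(1-p)\,(CN^{REF}_{normal}+CN^{ALT}_{normal})
         + p\,(CN^{REF}_{tumor}+CN^{ALT}_{tumor})}.$$

Its inverse (`deconvolve_counts()`) rescales each observed count by the
tumor share of that allele's producers. Germline-het locus:

$$REF_{tumor} = REF \cdot \frac{p\,CN^{REF}_{tumor}}{(1-p) + p\,CN^{REF}_{tumor}},
\qquad
ALT_{tumor} = ALT \cdot \frac{p\,CN^{ALT}_{tumor}}{(1-p) + p\,CN^{ALT}_{tumor}}.$$

Somatic locus (two normal REF-producing copies; every ALT read is
tumor-derived):

$$REF_{tumor} = REF \cdot \frac{p\,CN^{REF}_{tumor}}{2(1-p) + p\,CN^{REF}_{tumor}},
\qquad ALT_{tumor} = ALT,$$

and in both cases
$VAF_{tumor} = ALT_{tumor}/(REF_{tumor}+ALT_{tumor})$.

Three properties make this trustworthy and are enforced by tests:

* **Exact inversion.** Feeding expectation-valued counts back through the
  inverse returns the tumor copy fraction
  $CN^{ALT}_{tumor}/(CN^{REF}_{tumor}+CN^{ALT}_{tumor})$ to $10^{-12}$
  across a dense $(p, CN)$ grid, for both locus classes. This is why
  deconvoluted counts stay real-valued — they are expectations, and
  rounding them to integers would break the identity.
* **Limit identities.** $p=1$ returns the observed VAF; a balanced
  germline locus ($CN = (1,1)$) returns the observed VAF for any purity;
  $CN^{REF}_{tumor}=0$ at a somatic locus returns $VAF_{tumor}=1$ (every
  REF read attributed to contamination — the LOH pattern).
* **Oracle agreement.** An independent implementation that enumerates the
  four read-origin populations (normal-REF-haplotype, normal-ALT-haplotype,
  tumor-REF, tumor-ALT) and rescales agrees to $10^{-9}$ on random draws.

Purity $p \in (0, 1]$: $p = 1$ is legitimate (the correction becomes the
identity), $p = 0$ is rejected — with no tumor cells there is nothing to
deconvolute. Depth-zero loci are skipped with a logged reason rather than
failing a run; a somatic locus with ALT reads but $CN^{ALT}_{tumor}=0$ is
a copy-number/variant inconsistency, flagged with a warning and computed
with the given numbers (upstream segmentation can be wrong; silently
dropping data would hide that).

Point estimates are the deliverable; `vaf_confint()` adds an optional
parametric-bootstrap interval (binomial resampling of the observed counts,
1,000 seeded replicates by default) for users who want uncertainty — it is
a convenience layered on top of the estimator, not part of it.

## Allele-specific expression

If normal and tumor cells express the gene at the same per-copy rate (the
gene is not differentially expressed in the cohort) and transcript output
is proportional to template copy number, the same deconvolution applies to
RNA allelic counts. `ase_fold()` then compares the tumor-corrected RNA
allelic odds with the DNA copy-number odds:

$$fold = \frac{ALT^{RNA}_{tumor}/REF^{RNA}_{tumor}}
              {CN^{ALT}_{tumor}/CN^{REF}_{tumor}}.$$

The odds-ratio form was a genuine design choice: "expression relative to
the DNA-level expectation" admits several formalizations, and this one is
symmetric in the two alleles, reduces to exactly 1 under copy-proportional
expression, and multiplies correctly when factors compose. Under the
generator's forward model it is consistent for the per-copy expression
factor at somatic loci: if the somatically mutated copies transcribe at
rate $f$ relative to the others, the estimator's expectation is $f$ at any
purity and depth.

**Known attenuation at germline loci.** At a germline-het locus the
admixed normal cells carry both alleles and express them equally, so a
tumor-only expression bias is diluted; the estimator's expectation is

$$fold_{est} = \frac{(1-p) + p\,CN^{ALT}_{tumor} f}{(1-p) + p\,CN^{ALT}_{tumor}},$$

which shrinks toward 1 as purity falls (e.g. true $f = 0.3$ at
$p = 0.85$, $CN^{ALT} = 1$ reads as $0.41$). The *direction* of the effect
(repression vs over-expression) is always preserved. Recovery tests
therefore assert tight tolerances at somatic loci only; at germline loci
they check sign and monotonicity. Interpreting germline-locus folds from
low-purity specimens quantitatively would require inverting the expression
mixture too, which the package deliberately does not do.

When $CN^{REF}_{tumor} = 0$ or the corrected RNA REF count is zero the
fold is undefined and reported as an error ("complete silencing/loss of
REF copies") rather than as an arbitrarily capped number.

## Two-hit classification

A variant qualifies as a hit when it overlaps a coding interval of the
target gene by at least one base and its annotated effect is a
nonsynonymous SNV (nonsense or missense) or a frameshift indel; effects
are taken from upstream annotation, never recomputed from sequence, and
in-frame indels are excluded. Samples are then partitioned:
`two_hit` (germline + somatic qualifying variants), `somatic_only_LOH`
(somatic variant with $CN^{REF}_{tumor} = 0$ over the gene — biallelic
inactivation via loss of heterozygosity), `somatic_only_no_LOH`,
`germline_only`, `wild_type`; plus the binary mutant flag (any qualifying
variant). LOH is called from $CN^{REF}_{tumor} = 0$ exactly; a subclonal
value below 0.25 adds a "possible LOH" note without changing the status,
to avoid over-calling from noisy copy number. The rule admits missense
variants even though truncating variants dominate real two-hit genes;
truncating evidence (nonsense or frameshift) is marked separately in the
output so the stricter reading is recoverable.

## APOBEC tCw enrichment

Somatic SNVs passing a strict observed-VAF filter (VAF $> 0.05$; a variant
exactly at the threshold is dropped) are binned into the 96
pyrimidine-normalized trinucleotide classes, reading ±1 bp of reference
context and reverse-complementing purine-reference substitutions. The
enrichment score compares the TCW fraction (W = A or T) among C>T
mutations with the TCW fraction among background cytosines:

$$score = \frac{n_{tCw}\times background_C}{n_C \times background_{TCW}},$$

with a one-sided (greater) Fisher exact test on
$[[n_{tCw},\, n_C-n_{tCw}],\,[background_{TCW},\, background_C-background_{TCW}]]$.

Choices a user should know:

* **Mutation classes.** $n_C$ counts C>T mutations by default; some APOBEC
  analyses add C>G, available via `mutation_classes = c("C>T", "C>G")`.
  The classes used are recorded in the output.
* **Background window.** ±20 bp around each retained mutation, both
  strands; overlapping windows are merged so no base is counted twice.
* **Edge convention.** A motif is attributed to the position of its
  central cytosine: it counts when that C lies inside a window, with
  flanks read from the full reference even when they fall 1 bp outside.
  Mutation contexts are fetched from the genome the same way, so
  numerator and denominator are definitionally aligned; counting only
  motifs fully inside windows would bias the score upward by a few
  percent at 41-bp windows and detectably mis-calibrate the null.
* **Null calibration.** Mutations drawn uniformly over background
  cytosines give a median score within [0.9, 1.1] and approximately
  uniform one-sided p-values (Kolmogorov–Smirnov check). The calibration
  simulation uses 1,000 mutations per replicate — more than a typical
  sample carries — because the one-sided exact p is discrete and
  conservative at small counts, and only approaches the uniform as counts
  grow; testing exact uniformity at n = 150 would measure discreteness,
  not miscalibration.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions the recovery analyses
assume: 10 samples, 500 germline-het loci each, DNA and RNA depth 10,000,
purity drawn uniformly from 0.40–0.90, a segment copy-number menu of
diploid/gain/LOH states, scenario mix 4:1:1:4
(two_hit : somatic_LOH : germline_only : wild_type, the proportions of the
inactivation patterns the method is meant to distinguish), ASE factor 4
on the somatically mutated copies (inside the 2.3–7.9 fold range the
method should resolve), first-hit suppression factor 0.3 in the
germline-only scenario, and 150 somatic C>T passengers per sample with 60%
placed at TCW motifs. The toy reference (2 seeded contigs of 50 kb at
GC 0.4, with a two-exon target gene) is generated, never shipped.

Read counts are plain binomial draws at the forward-model expectation (a
beta-binomial overdispersion knob exists, default off — the model being
tested is deterministic in expectation, and overdispersion only widens
recovery intervals). RNA sampling draws per-copy transcript rates — copy
$i$ contributes weight $CN_i$ times its expression factor — which realizes
copy-proportional expression exactly when all factors are 1. In the
two-hit scenario the gene segment's REF/ALT orientation flips between the
germline and the somatic locus (the two hits sit on opposite haplotypes),
so the simulator emits a per-locus copy-number table carrying that phase;
the pipeline prefers it over the segment file, which is also how a real
analysis must resolve the major/minor-to-REF/ALT assignment that segment
callers leave implicit.

Passing recovery tests on these cohorts shows the estimators invert the
model they claim to invert, at realistic depths and purities, with exact
bookkeeping. It does *not* show robustness to what the simulator omits:
sequencing error and mapping bias, overdispersed counts, purity and
copy-number estimation error (purity and CN are inputs here, taken as
known), subclonal structure, or RNA-specific artifacts such as
allele-specific mapping bias. Errors in upstream purity/CN propagate
directly into $VAF_{tumor}$ and are not modeled.

## Numerical and bookkeeping choices

* Deconvoluted counts are real-valued expectations; no rounding anywhere.
* All coordinates are 1-based inclusive (VCF convention) in every file.
* Multi-allelic VCF records are rejected at read time with the offending
  position named — deconvolution is defined per ALT allele.
* Segment lookup is a binary search over sorted, non-overlapping segments;
  boundary positions are covered (inclusive on both ends), overlapping
  segments covering a locus are an error naming both.
* Every input locus ends up either in an output table or in the skip log
  with a stage and reason (conservation of records); reruns with the same
  inputs and options are byte-identical, and the generator is
  byte-identical under a fixed seed.
* Problem sizes in the test suite are chosen for a single CPU: the dense
  inversion grid (~2,000 parameter combinations), 1,000+ random oracle
  draws, one deep recovery cohort (10 × 500 loci at depth 10,000), an
  exhaustive Fisher-vs-enumeration sweep over all 2×2 tables with margins
  ≤ 20 plus 4,000 random tables with margins ≤ 50, and a 1,000-replicate
  null calibration.

## Limitations

* Purity and allele-specific copy number are consumed, not inferred; the
  package is downstream of purity/ploidy callers by design.
* ASE folds at germline-het loci are attenuated at low purity (derivation
  above); only somatic-locus folds are quantitatively calibrated.
* The two-hit classifier trusts the annotated effect labels; splice-site
  and regulatory hits are out of scope.
* The APOBEC stage implements the enrichment statistic only — no
  mutational-signature decomposition against a catalog.
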