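# Normal-cell copy mass producing REF reads vs ALT reads, fixed by locus
# class: a germline-het locus has one REF-bearing and one ALT-bearing copy
# per normal cell; at a somatic locus normal cells carry no ALT copy and
# both of their copies (including the one on the somatically mutated
# haplotype) read as REF.
.cn_normal <- function(locus_class) {
  germ <- locus_class == "germline_het"
  list(ref = ifelse(germ, 1, 2), alt = ifelse(germ, 1, 0))
}

.check_locus_class <- function(locus_class) {
  bad <- !locus_class %in% c("germline_het", "somatic")
  if (any(bad)) {
    stop("locus_class must be 'germline_het' or 'somatic', got: ",
         paste(unique(locus_class[bad]), collapse = ", "))
  }
  invisible(locus_class)
}

.check_purity <- function(purity) {
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("tumor purity must lie in (0, 1]")
  }
  invisible(purity)
}

.check_cn <- function(cn_ref, cn_alt) {
  if (any(!is.finite(cn_ref)) || any(!is.finite(cn_alt)) ||
      any(cn_ref < 0) || any(cn_alt < 0)) {
    stop("allele-specific copy numbers must be finite and non-negative")
  }
  if (any(cn_ref + cn_alt <= 0)) {
    stop("total tumor copy number cn_ref + cn_alt must be positive")
  }
  invisible(NULL)
}

#' Expected observed ALT allele fraction under tumor-normal admixture
#'
#' Forward admixture model: a specimen with tumor purity `p` mixes tumor
#' cells carrying `cn_ref` REF-bearing and `cn_alt` ALT-bearing copies of a
#' segment with diploid normal cells. The expected fraction of sequencing
#' reads supporting ALT is the ALT copy mass over the total copy mass:
#' \deqn{\frac{(1-p)\,CN^{ALT}_{normal} + p\,CN^{ALT}_{tumor}}
#'            {(1-p)(CN^{REF}_{normal}+CN^{ALT}_{normal}) +
#'             p(CN^{REF}_{tumor}+CN^{ALT}_{tumor})}}
#' with normal copy numbers fixed at (1, 1) for germline-het loci and (1, 0)
#' for somatic loci. This is the expectation that [deconvolve_counts()]
#' inverts, and the rate used by the read simulator.
#'
#' @param purity Tumor purity in (0, 1]; fraction of cells that are tumor.
#' @param cn_ref,cn_alt Non-negative tumor copy numbers of the REF-bearing
#'   and ALT-bearing copies (non-integer subclonal averages allowed).
#' @param locus_class `"germline_het"` or `"somatic"` (recycled).
#' @return Numeric vector of expected observed ALT fractions in \[0, 1\].
#' @examples
#' expected_observed_vaf(1, 1, 2, "germline_het")    # 2/3: pure tumor
#' expected_observed_vaf(0.5, 1, 2, "germline_het")  # 0.6
#' expected_observed_vaf(0.5, 1, 2, "somatic")       # 0.4
#' @export
expected_observed_vaf <- function(purity, cn_ref, cn_alt, locus_class) {
  .check_purity(purity)
  .check_cn(cn_ref, cn_alt)
  .check_locus_class(locus_class)
  n <- max(length(purity), length(cn_ref), length(cn_alt), length(locus_class))
  purity <- rep_len(purity, n); cn_ref <- rep_len(cn_ref, n)
  cn_alt <- rep_len(cn_alt, n); locus_class <- rep_len(locus_class, n)
  nrm <- .cn_normal(locus_class)
  num <- (1 - purity) * nrm$alt + purity * cn_alt
  den <- (1 - purity) * (nrm$ref + nrm$alt) + purity * (cn_ref + cn_alt)
  if (any(den <= 0)) stop("degenerate admixture: total copy mass is zero")
  num / den
}

#' Deconvolute observed allelic counts into tumor-only counts and VAF
#'
#' Removes the contribution of admixed normal cells from observed REF/ALT
#' read counts, given tumor purity and the tumor's allele-specific copy
#' number, and returns the intratumor VAF
#' \eqn{VAF_{tumor} = ALT_{tumor} / (REF_{tumor} + ALT_{tumor})}.
#'
#' At a germline-het locus each allele's reads are apportioned by the copy
#' mass each compartment contributes to that allele:
#' \deqn{REF_{tumor} = REF \cdot \frac{p\,CN^{REF}_{tumor}}
#'       {(1-p) + p\,CN^{REF}_{tumor}}, \qquad
#'       ALT_{tumor} = ALT \cdot \frac{p\,CN^{ALT}_{tumor}}
#'       {(1-p) + p\,CN^{ALT}_{tumor}}.}
#' At a somatic locus both normal copies read as REF, so
#' \deqn{REF_{tumor} = REF \cdot \frac{p\,CN^{REF}_{tumor}}
#'       {2(1-p) + p\,CN^{REF}_{tumor}}, \qquad ALT_{tumor} = ALT}
#' (every ALT read is tumor-derived).
#'
#' Deconvoluted counts are expectations and stay real-valued; rounding them
#' to integers would break the exact algebraic inversion of
#' [expected_observed_vaf()].
#'
#' @param ref_count,alt_count Non-negative observed read counts (vectors).
#' @param purity Tumor purity in (0, 1].
#' @param cn_ref,cn_alt Tumor allele-specific copy numbers.
#' @param locus_class `"germline_het"` or `"somatic"`.
#' @return A data.frame with columns `ref_tumor`, `alt_tumor`, `vaf_tumor`.
#'   `vaf_tumor` is NA (with a warning) where the deconvoluted depth is zero.
#' @examples
#' deconvolve_counts(40, 60, 0.5, 1, 2, "germline_het")  # vaf_tumor = 2/3
#' deconvolve_counts(60, 40, 0.5, 1, 2, "somatic")       # vaf_tumor = 2/3
#' @export
deconvolve_counts <- function(ref_count, alt_count, purity,
                              cn_ref, cn_alt, locus_class) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    stop("read counts must be non-negative")
  }
  if (any(ref_count + alt_count == 0)) {
    stop("depth-zero locus: no reads to deconvolute (filter such loci first)")
  }
  .check_purity(purity)
  .check_cn(cn_ref, cn_alt)
  .check_locus_class(locus_class)
  n <- max(length(ref_count), length(alt_count), length(purity),
           length(cn_ref), length(cn_alt), length(locus_class))
  ref_count <- rep_len(ref_count, n); alt_count <- rep_len(alt_count, n)
  purity <- rep_len(purity, n); cn_ref <- rep_len(cn_ref, n)
  cn_alt <- rep_len(cn_alt, n); locus_class <- rep_len(locus_class, n)

  somatic <- locus_class == "somatic"
  incons <- somatic & cn_alt == 0 & alt_count > 0
  if (any(incons)) {
    warning(sum(incons), " somatic locus/loci with alt reads but ",
            "cn_alt = 0: copy-number segmentation may be wrong at these loci")
  }

  # REF-side denominator: copy mass of all copies that read as REF.
  ref_den <- ifelse(somatic, 2 * (1 - purity), (1 - purity)) + purity * cn_ref
  ref_tumor <- ifelse(ref_den > 0,
                      ref_count * purity * cn_ref / ref_den, 0)
  alt_den <- (1 - purity) + purity * cn_alt
  alt_tumor <- ifelse(somatic, alt_count,
                      ifelse(alt_den > 0,
                             alt_count * purity * cn_alt / alt_den, 0))
  tot <- ref_tumor + alt_tumor
  vaf <- ifelse(tot > 0, alt_tumor / tot, NA_real_)
  if (anyNA(vaf)) {
    warning(sum(is.na(vaf)), " locus/loci with zero deconvoluted depth: ",
            "vaf_tumor undefined (NA)")
  }
  data.frame(ref_tumor = ref_tumor, alt_tumor = alt_tumor, vaf_tumor = vaf)
}

#' Allele-specific expression fold from tumor RNA allelic counts
#'
#' Applies the same purity/copy-number deconvolution to RNA allelic counts
#' and compares the tumor-corrected RNA allelic odds with the DNA
#' copy-number odds:
#' \deqn{fold = \frac{ALT^{RNA}_{tumor} / REF^{RNA}_{tumor}}
#'                   {CN^{ALT}_{tumor} / CN^{REF}_{tumor}}.}
#' Under copy-proportional expression the two odds coincide and `fold = 1`;
#' `fold > 1` means the ALT-bearing copies are over-expressed relative to
#' their copy number, `fold < 1` that they are repressed.
#'
#' The correction is valid only under the RNA-applicability conditions
#' checked by [ase_eligibility()]; the `eligible` flag is carried through
#' and a warning is emitted when it is `FALSE`.
#'
#' @param rna_ref,rna_alt Observed tumor-RNA allelic read counts (scalars).
#' @param purity Tumor purity in (0, 1].
#' @param cn_ref,cn_alt Tumor allele-specific copy numbers at the locus.
#' @param locus_class `"germline_het"` or `"somatic"`.
#' @param eligible Logical; result of [ase_eligibility()] for the gene.
#' @return A list of class `"ase_result"` with elements `fold`,
#'   `rna_vaf_tumor`, `dna_copy_fraction`, `eligible`.
#' @examples
#' # RNA odds exactly match copy odds: no allele-specific expression
#' ase_fold(60, 40, 0.5, 1, 2, "somatic")$fold            # 1
#' ase_fold(20, 80, 0.5, 1, 2, "somatic")$fold            # 6
#' ase_fold(80, 20, 0.5, 1, 1, "germline_het")$fold       # 0.25
#' @export
ase_fold <- function(rna_ref, rna_alt, purity, cn_ref, cn_alt, locus_class,
                     eligible = TRUE) {
  stopifnot(length(rna_ref) == 1, length(rna_alt) == 1)
  if (rna_ref + rna_alt == 0) stop("depth-zero RNA locus")
  if (cn_ref == 0) {
    stop("cn_ref = 0: ASE fold undefined (no REF-bearing tumor copies; ",
         "complete loss of the REF allele)")
  }
  dec <- deconvolve_counts(rna_ref, rna_alt, purity, cn_ref, cn_alt,
                           locus_class)
  if (dec$ref_tumor == 0) {
    stop("corrected RNA REF count is 0: ASE fold undefined ",
         "(complete silencing of REF copies)")
  }
  if (!isTRUE(eligible)) {
    warning("RNA-applicability conditions not met for this gene; ",
            "ASE fold is reported but may be confounded")
  }
  structure(list(
    fold = (dec$alt_tumor / dec$ref_tumor) / (cn_alt / cn_ref),
    rna_vaf_tumor = dec$vaf_tumor,
    dna_copy_fraction = cn_alt / (cn_ref + cn_alt),
    eligible = isTRUE(eligible)
  ), class = "ase_result")
}

#' @export
print.ase_result <- function(x, ...) {
  cat(sprintf(
    "ASE fold: %.3f (RNA vaf_tumor %.3f vs DNA copy fraction %.3f)%s\n",
    x$fold, x$rna_vaf_tumor, x$dna_copy_fraction,
    if (x$eligible) "" else " [NOT eligible]"))
  invisible(x)
}

#' RNA-applicability conditions for allele-specific expression analysis
#'
#' The purity/copy-number correction can be applied to RNA allelic counts
#' only when (i) the gene is not differentially expressed between tumor and
#' normal cells in the cohort (so admixed normal cells express it at the
#' tumor rate), and (ii) transcript output is assumed proportional to
#' template copy number. DEG status is computed outside this package and
#' passed in.
#'
#' @param gene_is_deg Logical; is the gene a cohort-level DEG?
#' @param proportional_expression_assumed Logical; is copy-proportional
#'   expression a tenable assumption for this gene?
#' @return `TRUE` iff both conditions hold.
#' @export
ase_eligibility <- function(gene_is_deg, proportional_expression_assumed) {
  stopifnot(is.logical(gene_is_deg), is.logical(proportional_expression_assumed),
            length(gene_is_deg) == 1, length(proportional_expression_assumed) == 1,
            !is.na(gene_is_deg), !is.na(proportional_expression_assumed))
  !gene_is_deg && proportional_expression_assumed
}

#' Parametric-bootstrap confidence interval for the intratumor VAF
#'
#' Optional uncertainty companion to [deconvolve_counts()] (the
#' deconvolution itself reports point estimates only): resamples the
#' observed ALT count as Binomial(depth, alt/depth), re-deconvolutes each
#' replicate, and returns percentile quantiles of `vaf_tumor`.
#'
#' @param ref_count,alt_count Observed counts at one locus.
#' @param purity,cn_ref,cn_alt,locus_class As in [deconvolve_counts()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param conf Two-sided confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return Named vector `c(lower, estimate, upper)`.
#' @export
vaf_confint <- function(ref_count, alt_count, purity, cn_ref, cn_alt,
                        locus_class, n_boot = 1000, conf = 0.95, seed = 1L) {
  stopifnot(length(ref_count) == 1, length(alt_count) == 1, n_boot >= 2)
  depth <- ref_count + alt_count
  if (depth == 0) stop("depth-zero locus")
  est <- deconvolve_counts(ref_count, alt_count, purity, cn_ref, cn_alt,
                           locus_class)$vaf_tumor
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  alt_star <- stats::rbinom(n_boot, depth, alt_count / depth)
  keep <- alt_star > 0 | ref_count > 0  # all-zero replicates impossible here
  reps <- deconvolve_counts(depth - alt_star[keep], alt_star[keep], purity,
                            cn_ref, cn_alt, locus_class)$vaf_tumor
  q <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       na.rm = TRUE, names = FALSE)
  c(lower = q[1], estimate = est, upper = q[2])
}

# Save/restore the RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
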