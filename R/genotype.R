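#' Build a minimal gene model for coding-region overlap tests
#'
#' Holds the coding intervals (1-based, inclusive) of one gene; used to
#' decide whether a variant falls "in the coding region".
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome/contig name.
#' @param starts,ends Integer vectors of coding-interval bounds (1-based,
#'   inclusive); must be non-overlapping.
#' @param strand `"+"` or `"-"` (annotation only; overlap is strand-blind).
#' @return A list of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, starts, ends, strand = "+") {
  stopifnot(length(starts) == length(ends), all(starts <= ends),
            strand %in% c("+", "-"))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)])) {
    stop("coding intervals overlap")
  }
  structure(list(gene_id = gene_id, chrom = chrom,
                 starts = as.integer(starts), ends = as.integer(ends),
                 strand = strand),
            class = "gene_model")
}

#' Read a gene model from a BED-like coding-interval file
#'
#' Tab-delimited with header columns `gene_id, chrom, start, end, strand`;
#' coordinates 1-based inclusive.
#'
#' @param path File path.
#' @param gene_id Gene to extract (default: the only gene in the file).
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, gene_id = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(gene_id)) {
    gene_id <- unique(d$gene_id)
    if (length(gene_id) != 1) stop("file holds several genes; pick one")
  }
  d <- d[d$gene_id == gene_id, , drop = FALSE]
  if (nrow(d) == 0) stop("gene ", gene_id, " not in ", path)
  gene_model(gene_id, d$chrom[1], d$start, d$end, d$strand[1])
}

.qualifying_effects <- c("nonsense", "missense", "frameshift_indel")
.known_effects <- c(.qualifying_effects,
                    "inframe_indel", "synonymous", "noncoding")
.truncating_effects <- c("nonsense", "frameshift_indel")

#' Does a variant qualify as an inactivating hit on a gene?
#'
#' A variant qualifies when it overlaps a coding interval of the gene by at
#' least one base and its annotated effect is a nonsynonymous SNV (nonsense
#' or missense) or a frameshift indel. Effect labels come from upstream
#' annotation and are not recomputed from sequence; in-frame indels,
#' synonymous and noncoding variants never qualify.
#'
#' @param chrom,pos Variant location (1-based). For indels the affected
#'   interval is `pos .. pos + nchar(ref) - 1`.
#' @param ref,alt Variant alleles (used only for the indel span).
#' @param effect One of `"nonsense"`, `"missense"`, `"frameshift_indel"`,
#'   `"inframe_indel"`, `"synonymous"`, `"noncoding"`.
#' @param gene A [gene_model()].
#' @return Logical vector: qualifies as a hit.
#' @export
classify_variant_effect <- function(chrom, pos, ref, alt, effect, gene) {
  stopifnot(inherits(gene, "gene_model"))
  if (any(!effect %in% .known_effects)) {
    stop("unknown effect label(s): ",
         paste(setdiff(unique(effect), .known_effects), collapse = ", "))
  }
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(effect))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  effect <- rep_len(effect, n)
  span_end <- pos + pmax(nchar(ref), 1L) - 1L
  overlaps <- vapply(seq_len(n), function(i) {
    chrom[i] == gene$chrom &&
      any(pos[i] <= gene$ends & span_end[i] >= gene$starts)
  }, logical(1))
  overlaps & effect %in% .qualifying_effects
}

#' Classify a sample's two-hit inactivation state of a target gene
#'
#' Applies [classify_variant_effect()] to the sample's variants in the
#' target gene, then assigns one of five states:
#' \describe{
#'   \item{two_hit}{at least one qualifying germline and one qualifying
#'     somatic variant (classical biallelic inactivation).}
#'   \item{somatic_only_LOH}{qualifying somatic variant(s) only, with
#'     complete loss of the REF-bearing (wild-type) copies
#'     (`cn_ref_tumor = 0`) — biallelic inactivation via LOH.}
#'   \item{somatic_only_no_LOH}{qualifying somatic variant(s) only, with
#'     the wild-type copy retained or copy number unavailable.}
#'   \item{germline_only}{qualifying germline variant(s) only.}
#'   \item{wild_type}{no qualifying variant.}
#' }
#' `mut_flag` is the binary mutant/wild-type call: `TRUE` iff any
#' qualifying variant exists. LOH is called from `cn_ref_tumor == 0`
#' exactly; a subclonal near-zero value (< 0.25) adds a `"possible LOH"`
#' note without changing the status.
#'
#' @param variants data.frame with columns `variant_id, chrom, pos, ref,
#'   alt, origin` (`"germline"`/`"somatic"`), `effect`.
#' @param gene A [gene_model()].
#' @param cn_ref_tumor,cn_alt_tumor Allele-specific copy number over the
#'   gene (REF-bearing copies relative to the somatic variant); `NA` when
#'   unavailable, which degrades LOH resolution.
#' @param sample_id Sample label carried into the result.
#' @return One-row data.frame: `sample_id, status, mut_flag, n_germline,
#'   n_somatic, evidence` (comma-joined qualifying variant ids, truncating
#'   ones marked `*`), `notes`.
#' @export
classify_sample_genotype <- function(variants, gene,
                                     cn_ref_tumor = NA_real_,
                                     cn_alt_tumor = NA_real_,
                                     sample_id = "sample") {
  stopifnot(inherits(gene, "gene_model"))
  notes <- character(0)
  if (nrow(variants) > 0) {
    stopifnot(all(variants$origin %in% c("germline", "somatic")))
    hit <- classify_variant_effect(variants$chrom, variants$pos,
                                   variants$ref, variants$alt,
                                   variants$effect, gene)
    q <- variants[hit, , drop = FALSE]
  } else {
    q <- variants
  }
  n_germ <- sum(q$origin == "germline")
  n_som <- sum(q$origin == "somatic")
  loh <- !is.na(cn_ref_tumor) && cn_ref_tumor == 0
  if (is.na(cn_ref_tumor)) {
    notes <- c(notes, "no copy-number estimate at gene: LOH not assessable")
  } else if (!loh && cn_ref_tumor < 0.25) {
    notes <- c(notes, sprintf("possible LOH (cn_ref_tumor = %.2f)",
                              cn_ref_tumor))
  }
  status <- if (n_germ > 0 && n_som > 0) {
    "two_hit"
  } else if (n_som > 0) {
    if (loh) "somatic_only_LOH" else "somatic_only_no_LOH"
  } else if (n_germ > 0) {
    "germline_only"
  } else {
    "wild_type"
  }
  evid <- if (nrow(q) > 0) {
    marks <- ifelse(q$effect %in% .truncating_effects, "*", "")
    paste0(q$origin, ":", q$variant_id, marks, collapse = ",")
  } else ""
  data.frame(sample_id = sample_id, status = status,
             mut_flag = nrow(q) > 0,
             n_germline = n_germ, n_somatic = n_som,
             evidence = evid,
             notes = paste(notes, collapse = "; "),
             stringsAsFactors = FALSE)
}
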