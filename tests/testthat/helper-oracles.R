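# Independent oracles, deliberately written in a different style from the
# package implementation.

# Read-origin enumeration: list every copy population (normal-REF-haplotype,
# normal-ALT-haplotype, tumor-REF, tumor-ALT) with its copy mass, decide
# which base each population contributes reads for, and rescale the observed
# counts by the tumor share of each base's producers.
oracle_deconvolve <- function(ref_count, alt_count, p, cn_ref, cn_alt,
                              locus_class) {
  origins <- data.frame(
    who = c("normal_ref_hap", "normal_alt_hap", "tumor_ref", "tumor_alt"),
    mass = c((1 - p) * 1, (1 - p) * 1, p * cn_ref, p * cn_alt),
    tumor = c(FALSE, FALSE, TRUE, TRUE))
  origins$base <- if (locus_class == "germline_het") {
    c("REF", "ALT", "REF", "ALT")
  } else {
    # somatic: both normal haplotypes read as REF at this position
    c("REF", "REF", "REF", "ALT")
  }
  share <- function(base) {
    prod <- origins[origins$base == base, ]
    if (sum(prod$mass) == 0) return(0)
    sum(prod$mass[prod$tumor]) / sum(prod$mass)
  }
  rt <- ref_count * share("REF")
  at <- alt_count * share("ALT")
  list(ref_tumor = rt, alt_tumor = at,
       vaf_tumor = if (rt + at > 0) at / (rt + at) else NA_real_)
}

# One-sided (greater) Fisher p for table [[a, b], [c, d]] as an explicit
# hypergeometric tail sum over more-extreme tables, via log-choose.
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- a:min(r1, c1)
  ks <- ks[r1 - ks <= n - c1]
  sum(exp(lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)))
}

# Character-level scan over one interval of a full sequence: cytosines and
# TCW motifs on both strands (reference-strand G is a minus-strand C; WGA
# is a minus-strand TCW). A motif counts when its central C/G lies in
# [from, to]; flanks are read from the full sequence.
oracle_count_contexts <- function(full_seq, from = 1,
                                  to = nchar(full_seq)) {
  s <- strsplit(full_seq, "")[[1]]
  n <- length(s)
  cc <- 0L; tcw <- 0L
  for (i in from:to) {
    if (s[i] %in% c("C", "G")) cc <- cc + 1L
    if (i > 1 && i < n) {
      if (s[i] == "C" && s[i - 1] == "T" && s[i + 1] %in% c("A", "T")) {
        tcw <- tcw + 1L
      }
      if (s[i] == "G" && s[i - 1] %in% c("A", "T") && s[i + 1] == "A") {
        tcw <- tcw + 1L
      }
    }
  }
  list(background_TCW = tcw, background_C = cc)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")
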