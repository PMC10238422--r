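.base_comp <- c(A = "T", C = "G", G = "C", T = "A")
.substitutions <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 pyrimidine-normalized trinucleotide substitution classes
#'
#' Canonical order: six substitution types (`C>A, C>G, C>T, T>A, T>C, T>G`)
#' each crossed with the 16 flanking-base combinations, e.g. `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
trinuc_classes <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(.substitutions, function(s) {
    as.vector(t(outer(bases, bases, function(u, d)
      paste0(u, "[", s, "]", d))))
  }))
}

#' Normalize a substitution and its context to the pyrimidine strand
#'
#' The 96-class matrix stores every single-base substitution with the
#' mutated base as a pyrimidine (C or T). A purine reference base is
#' complemented together with its alternate, and the flanking context is
#' reverse-complemented (the 5' flank of the pyrimidine strand is the
#' complement of the purine strand's 3' flank).
#'
#' @param ref,alt Reference and alternate bases (single characters,
#'   vectors allowed); must differ.
#' @param upstream,downstream The bases immediately 5' and 3' of the
#'   variant on the reference strand.
#' @return Character vector of class labels such as `"T[C>T]A"`; `NA` where
#'   any base is ambiguous (not A/C/G/T).
#' @examples
#' normalize_substitution("C", "T", "A", "A")  # "A[C>T]A"
#' normalize_substitution("G", "A", "T", "A")  # "T[C>T]A"
#' normalize_substitution("A", "C", "C", "G")  # "C[T>G]G"
#' @export
normalize_substitution <- function(ref, alt, upstream, downstream) {
  n <- max(length(ref), length(alt), length(upstream), length(downstream))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  up <- toupper(rep_len(upstream, n)); dn <- toupper(rep_len(downstream, n))
  if (any(ref == alt)) stop("ref and alt must differ")
  ok <- ref %in% names(.base_comp) & alt %in% names(.base_comp) &
    up %in% names(.base_comp) & dn %in% names(.base_comp)
  out <- rep(NA_character_, n)
  flip <- ok & ref %in% c("A", "G")
  r <- ref; a <- alt; u <- up; d <- dn
  r[flip] <- .base_comp[ref[flip]]
  a[flip] <- .base_comp[alt[flip]]
  u[flip] <- .base_comp[dn[flip]]
  d[flip] <- .base_comp[up[flip]]
  out[ok] <- paste0(u[ok], "[", r[ok], ">", a[ok], "]", d[ok])
  out
}

.class_parts <- function(classes) {
  list(up = substr(classes, 1, 1),
       sub = substr(classes, 3, 5),
       down = substr(classes, 7, 7))
}

#' Build the per-sample 96-class trinucleotide mutation matrix
#'
#' Filters somatic SNVs at the observed-VAF threshold (strictly greater
#' than `vaf_filter`, so a variant exactly at the threshold is dropped),
#' fetches the +/-1 bp reference context, normalizes each substitution to
#' the pyrimidine strand, and tabulates counts over the 96 classes.
#' Variants at a contig edge (no flanking base) or with ambiguous context
#' are skipped and reported.
#'
#' @param snvs data.frame with columns `sample_id, chrom, pos, ref, alt,
#'   vaf` (single-base ref and alt only).
#' @param genome A [Biostrings::DNAStringSet] covering all loci, names
#'   matching `chrom`.
#' @param vaf_filter Retain variants with `vaf > vaf_filter` (default 0.05).
#' @return Object of class `"trinuc_matrix"`: list with `counts` (samples
#'   x 96 integer matrix), `n_total` (per-sample totals), `skipped`
#'   (data.frame of dropped loci with reasons), `vaf_filter`.
#' @export
build_trinucleotide_matrix <- function(snvs, genome, vaf_filter = 0.05) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "vaf")
  stopifnot(all(need %in% names(snvs)))
  if (any(nchar(snvs$ref) != 1 | nchar(snvs$alt) != 1)) {
    stop("build_trinucleotide_matrix expects SNVs (1-bp ref and alt)")
  }
  samples <- sort(unique(as.character(snvs$sample_id)))
  classes <- trinuc_classes()
  counts <- matrix(0L, nrow = length(samples), ncol = length(classes),
                   dimnames = list(samples, classes))
  skip_df <- function(sample_id, chrom, pos, reason) {
    data.frame(sample_id = as.character(sample_id),
               chrom = as.character(chrom), pos = pos,
               reason = rep_len(reason, length(pos)),
               stringsAsFactors = FALSE)
  }
  keep <- snvs$vaf > vaf_filter
  skipped <- skip_df(snvs$sample_id[!keep], snvs$chrom[!keep],
                     snvs$pos[!keep], "vaf_filter")
  d <- snvs[keep, , drop = FALSE]
  if (nrow(d) > 0) {
    seq_chr <- lapply(as.character(genome), identity)  # character cache
    names(seq_chr) <- names(genome)
    if (any(!d$chrom %in% names(seq_chr))) {
      stop("reference does not cover contig(s): ",
           paste(setdiff(unique(d$chrom), names(seq_chr)), collapse = ", "))
    }
    len <- nchar(unlist(seq_chr))[d$chrom]
    edge <- d$pos <= 1 | d$pos >= len
    skipped <- rbind(skipped, skip_df(d$sample_id[edge], d$chrom[edge],
                                      d$pos[edge], "contig_edge"))
    d <- d[!edge, , drop = FALSE]
  }
  if (nrow(d) > 0) {
    ctx <- vapply(seq_len(nrow(d)), function(i)
      substr(seq_chr[[d$chrom[i]]], d$pos[i] - 1L, d$pos[i] + 1L),
      character(1))
    cls <- normalize_substitution(d$ref, d$alt,
                                  substr(ctx, 1, 1), substr(ctx, 3, 3))
    amb <- is.na(cls)
    skipped <- rbind(skipped, skip_df(d$sample_id[amb], d$chrom[amb],
                                      d$pos[amb], "ambiguous_base"))
    d <- d[!amb, , drop = FALSE]; cls <- cls[!amb]
    if (nrow(d) > 0) {
      tab <- table(factor(as.character(d$sample_id), levels = samples),
                   factor(cls, levels = classes))
      counts <- counts + unclass(tab)
    }
  }
  structure(list(counts = counts, n_total = rowSums(counts),
                 skipped = skipped, vaf_filter = vaf_filter),
            class = "trinuc_matrix")
}

#' @export
print.trinuc_matrix <- function(x, ...) {
  cat(sprintf(
    "96-class trinucleotide matrix: %d sample(s), %d mutation(s) (%d skipped, VAF filter > %g)\n",
    nrow(x$counts), sum(x$n_total), nrow(x$skipped), x$vaf_filter))
  invisible(x)
}

#' Count background cytosines and TCW motifs around mutation loci
#'
#' Examines a +/-`window` bp reference window around each retained mutation
#' (windows clipped to contig bounds and merged where they overlap, so no
#' base is counted twice) and counts, on both strands: cytosines
#' (`background_C` = C plus G on the reference strand) and TCW motifs with
#' W in \{A, T\} (`background_TCW` = plus-strand `TCW` plus minus-strand
#' motifs, i.e. reference-strand `WGA`). These are the denominator contexts
#' of the APOBEC enrichment score.
#'
#' A motif is attributed to the position of its central (mutable) cytosine:
#' it counts when that cytosine lies inside a window, with the flanking
#' bases read from the full reference even when they fall just outside.
#' This mirrors how mutation contexts are fetched and keeps the score
#' unbiased at window edges.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param loci data.frame with columns `chrom, pos` (1-based).
#' @param window Half-width in bp (default 20).
#' @return List of class `"background_contexts"` with `background_TCW`,
#'   `background_C`, `n_bases` (merged footprint size).
#' @export
count_background_contexts <- function(genome, loci, window = 20) {
  stopifnot(window >= 1)
  if (nrow(loci) == 0) stop("empty loci list: no background to count")
  if (any(!loci$chrom %in% names(genome))) {
    stop("reference does not cover contig(s): ",
         paste(setdiff(unique(loci$chrom), names(genome)), collapse = ", "))
  }
  tcw <- 0L; cc <- 0L; nb <- 0L
  for (chr in unique(loci$chrom)) {
    pos <- loci$pos[loci$chrom == chr]
    L <- length(genome[[chr]])
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, pos - window), end = pmin(L, pos + window)))
    for (i in seq_along(ir)) {
      s0 <- IRanges::start(ir)[i]; e0 <- IRanges::end(ir)[i]
      f <- Biostrings::alphabetFrequency(
        Biostrings::subseq(genome[[chr]], s0, e0))
      cc <- cc + f[["C"]] + f[["G"]]
      nb <- nb + e0 - s0 + 1L
      # flanks may reach 1 bp beyond the window; the central base may not
      es <- max(1L, s0 - 1L); ee <- min(L, e0 + 1L)
      ext <- Biostrings::subseq(genome[[chr]], es, ee)
      for (pat in c("TCW", "WGA")) {
        st <- IRanges::start(Biostrings::matchPattern(pat, ext,
                                                      fixed = FALSE))
        centers <- es + st  # genome position of the central C (or G)
        tcw <- tcw + sum(centers >= s0 & centers <= e0)
      }
    }
  }
  structure(list(background_TCW = as.integer(tcw),
                 background_C = as.integer(cc),
                 n_bases = as.integer(nb)),
            class = "background_contexts")
}

#' APOBEC tCw enrichment score and one-sided Fisher exact test
#'
#' APOBEC cytidine deaminases preferentially mutate cytosines in the TCW
#' motif (W = A or T). The enrichment score compares the TCW fraction among
#' the sample's C>T mutations with the TCW fraction among background
#' cytosines:
#' \deqn{score = \frac{n_{tCw} \times background_C}
#'                    {n_C \times background_{TCW}}}
#' where `n_C` counts mutations in `mutation_classes` (default C>T) and
#' `n_tCw` the subset whose context has 5' T and 3' A/T. Significance is a
#' one-sided (greater) Fisher exact test on
#' `[[n_tCw, n_C - n_tCw], [background_TCW, background_C - background_TCW]]`.
#'
#' Some APOBEC analyses also count C>G mutations; pass
#' `mutation_classes = c("C>T", "C>G")` for that convention. The classes
#' used are recorded in the result.
#'
#' @param counts Named numeric vector over the 96 classes (one row of a
#'   [build_trinucleotide_matrix()] result), or a `trinuc_matrix` together
#'   with `sample`.
#' @param background A [count_background_contexts()] result (or list with
#'   `background_TCW`, `background_C`).
#' @param mutation_classes Substitution types entering the statistic.
#' @param sample Sample name when `counts` is a `trinuc_matrix`.
#' @return List of class `"apobec_enrichment"`: `score, n_tCw, n_C,
#'   background_TCW, background_C, p_value, table, mutation_classes`.
#' @examples
#' bg <- list(background_TCW = 100, background_C = 400)
#' cnt <- setNames(numeric(96), trinuc_classes())
#' cnt["T[C>T]A"] <- 15; cnt["A[C>T]G"] <- 5
#' apobec_enrichment(cnt, bg)$score  # (15*400)/(20*100) = 3
#' @export
apobec_enrichment <- function(counts, background,
                              mutation_classes = "C>T", sample = NULL) {
  if (inherits(counts, "trinuc_matrix")) {
    if (is.null(sample)) {
      if (nrow(counts$counts) != 1)
        stop("several samples in matrix: pass `sample`")
      sample <- rownames(counts$counts)[1]
    }
    counts <- counts$counts[sample, ]
  }
  stopifnot(length(counts) == 96,
            all(names(counts) == trinuc_classes()),
            all(mutation_classes %in% .substitutions))
  bT <- background$background_TCW; bC <- background$background_C
  if (is.null(bT) || is.null(bC) || bC <= 0 || bT <= 0 || bT > bC) {
    stop("invalid background: need 0 < background_TCW <= background_C")
  }
  parts <- .class_parts(names(counts))
  in_cls <- parts$sub %in% mutation_classes
  n_C <- sum(counts[in_cls])
  if (n_C == 0) stop("no mutations in the requested classes: score undefined")
  n_tCw <- sum(counts[in_cls & parts$up == "T" & parts$down %in% c("A", "T")])
  tab <- matrix(c(n_tCw, n_C - n_tCw, bT, bC - bT),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("mutations", "background"),
                                c("TCW", "other_C")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(score = (n_tCw * bC) / (n_C * bT),
                 n_tCw = n_tCw, n_C = n_C,
                 background_TCW = bT, background_C = bC,
                 p_value = p, table = tab,
                 mutation_classes = mutation_classes),
            class = "apobec_enrichment")
}

#' @export
print.apobec_enrichment <- function(x, ...) {
  cat(sprintf(
    "APOBEC enrichment: score %.3f (n_tCw %d / n_C %d vs background %d / %d), one-sided Fisher p = %.4g [classes: %s]\n",
    x$score, x$n_tCw, x$n_C, x$background_TCW, x$background_C, x$p_value,
    paste(x$mutation_classes, collapse = ",")))
  invisible(x)
}
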