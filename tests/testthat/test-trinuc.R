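test_that("substitutions normalize to the pyrimidine strand", {
  expect_equal(normalize_substitution("C", "T", "A", "A"), "A[C>T]A")
  # purine reference: complement the substitution, reverse-complement context
  expect_equal(normalize_substitution("G", "A", "T", "A"), "T[C>T]A")
  expect_equal(normalize_substitution("A", "C", "C", "G"), "C[T>G]G")
  expect_true(is.na(normalize_substitution("C", "T", "N", "A")))
  expect_error(normalize_substitution("C", "C", "A", "A"), "must differ")
  # all 96 classes are distinct and every class has a pyrimidine center
  cls <- trinuc_classes()
  expect_length(unique(cls), 96)
  expect_true(all(substr(cls, 3, 3) %in% c("C", "T")))
})

test_that("matrix counts conserve filtered SNVs and respect the strict VAF filter", {
  genome <- Biostrings::DNAStringSet(c(chrA = "TTACATTCAGGT"))
  snvs <- data.frame(
    sample_id = "s1",
    chrom = "chrA",
    pos = c(4, 8, 10, 4, 1, 12),
    ref = c("C", "C", "G", "C", "T", "T"),
    alt = c("T", "T", "A", "A", "G", "C"),
    vaf = c(0.3, 0.051, 0.4, 0.05, 0.3, 0.3))  # 0.05 exactly is dropped
  tm <- build_trinucleotide_matrix(snvs, genome, vaf_filter = 0.05)
  # retained: pos 4 C>T (ACA), pos 8 C>T (TCA), pos 10 G>A (AGG -> C[C>T]T);
  # dropped: pos 4 at the threshold, pos 1 and 12 at contig edges
  expect_equal(unname(tm$n_total["s1"]), 3)
  expect_equal(unname(tm$counts["s1", "A[C>T]A"]), 1)
  expect_equal(unname(tm$counts["s1", "T[C>T]A"]), 1)
  expect_equal(unname(tm$counts["s1", "C[C>T]T"]), 1)
  expect_equal(sort(tm$skipped$reason),
               c("contig_edge", "contig_edge", "vaf_filter"))
  expect_equal(sum(tm$counts), sum(tm$n_total))
})

test_that("the matrix is invariant under reverse-complementing the reference", {
  set.seed(53)
  L <- 400
  seqs <- paste(sample(c("A", "C", "G", "T"), L, TRUE,
                       prob = c(.3, .2, .2, .3)), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrA = seqs))
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- names(genome)
  pos <- sample(2:(L - 1), 40)
  ref <- vapply(pos, function(p) substr(seqs, p, p), character(1))
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  snvs <- data.frame(sample_id = "s", chrom = "chrA", pos = pos,
                     ref = ref, alt = alt, vaf = 0.5)
  flipped <- data.frame(sample_id = "s", chrom = "chrA",
                        pos = L - pos + 1,
                        ref = unname(comp_base[ref]),
                        alt = unname(comp_base[alt]), vaf = 0.5)
  m1 <- build_trinucleotide_matrix(snvs, genome)
  m2 <- build_trinucleotide_matrix(flipped, rc)
  expect_equal(m1$counts, m2$counts)
})

test_that("background context counting matches a character-level scan", {
  # worked 6-mer: C at 2 and 5, G at 6 (minus-strand C), one TCW at 1-3
  genome <- Biostrings::DNAStringSet(c(chrA = "TCATCG"))
  bg <- count_background_contexts(genome,
                                  data.frame(chrom = "chrA", pos = 3),
                                  window = 5)
  expect_equal(bg$background_C, 3)
  expect_equal(bg$background_TCW, 1)
  # degenerate background without any cytosine
  noc <- Biostrings::DNAStringSet(c(chrA = "ATTATAAT"))
  bg0 <- count_background_contexts(noc,
                                   data.frame(chrom = "chrA", pos = 4),
                                   window = 4)
  expect_equal(bg0$background_C, 0)
  cnt <- stats::setNames(numeric(96), trinuc_classes())
  cnt["T[C>T]A"] <- 3
  expect_error(apobec_enrichment(cnt, bg0), "background")
  expect_error(count_background_contexts(genome,
                                         data.frame(chrom = character(0),
                                                    pos = integer(0))),
               "empty loci")
})

test_that("overlapping windows are merged, never double-counted", {
  set.seed(59)
  L <- 300
  seqs <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrA = seqs))
  # two loci 10 bp apart with window 20: merged footprint 41 + 10 bp
  loci <- data.frame(chrom = "chrA", pos = c(100, 110))
  got <- count_background_contexts(genome, loci, window = 20)
  want <- oracle_count_contexts(seqs, 80, 130)
  expect_equal(got$background_C, want$background_C)
  expect_equal(got$background_TCW, want$background_TCW)
  expect_equal(got$n_bases, 51)
  # and in general: random locus sets vs oracle over merged intervals
  for (i in 1:20) {
    pos <- sort(sample(25:(L - 25), 5))
    got <- count_background_contexts(genome,
                                     data.frame(chrom = "chrA", pos = pos),
                                     window = 20)
    ir <- IRanges::reduce(IRanges::IRanges(pos - 20, pos + 20))
    want <- lapply(seq_along(ir), function(j)
      oracle_count_contexts(seqs, IRanges::start(ir)[j],
                            IRanges::end(ir)[j]))
    expect_equal(got$background_C, sum(vapply(want, `[[`, 0,
                                              "background_C")))
    expect_equal(got$background_TCW, sum(vapply(want, `[[`, 0,
                                                "background_TCW")))
  }
})

test_that("enrichment score reproduces the printed formula and its null", {
  cnt <- stats::setNames(numeric(96), trinuc_classes())
  cnt["T[C>T]A"] <- 10; cnt["T[C>T]T"] <- 5   # n_tCw = 15
  cnt["A[C>T]G"] <- 3; cnt["G[C>T]C"] <- 2    # other C>T
  bg <- list(background_TCW = 100, background_C = 400)
  enr <- apobec_enrichment(cnt, bg)
  expect_equal(enr$n_tCw, 15)
  expect_equal(enr$n_C, 20)
  expect_equal(enr$score, (15 * 400) / (20 * 100))  # 3.0, exactly
  expect_equal(unname(enr$table[1, ]), c(15, 5))
  expect_equal(unname(enr$table[2, ]), c(100, 300))
  # C>G mutations are excluded under the default classes
  cnt["T[C>G]A"] <- 50
  expect_equal(apobec_enrichment(cnt, bg)$n_C, 20)
  expect_equal(apobec_enrichment(cnt, bg,
                                 mutation_classes = c("C>T", "C>G"))$n_C, 70)
  # proportional case: score exactly 1
  cnt0 <- stats::setNames(numeric(96), trinuc_classes())
  cnt0["T[C>T]A"] <- 5; cnt0["A[C>T]G"] <- 15
  expect_equal(apobec_enrichment(cnt0, bg)$score, 1)
  # no mutations in the requested classes
  cntT <- stats::setNames(numeric(96), trinuc_classes())
  cntT["A[T>C]A"] <- 4
  expect_error(apobec_enrichment(cntT, bg), "no mutations")
})

test_that("one-sided Fisher p equals the hypergeometric tail oracle", {
  # the worked table
  cnt <- stats::setNames(numeric(96), trinuc_classes())
  cnt["T[C>T]A"] <- 15; cnt["A[C>T]G"] <- 5
  bg <- list(background_TCW = 100, background_C = 400)
  enr <- apobec_enrichment(cnt, bg)
  expect_equal(enr$p_value, oracle_fisher_greater(15, 5, 100, 300),
               tolerance = 1e-9)
  # exhaustive over small tables, routed through the package path (the
  # full sweep at larger margins lives in the acceptance suite)
  cls <- trinuc_classes()
  enrich_p <- function(a, b, c, d) {
    cnt <- stats::setNames(numeric(96), cls)
    cnt["T[C>T]A"] <- a; cnt["A[C>T]G"] <- b
    apobec_enrichment(cnt, list(background_TCW = c,
                                background_C = c + d))$p_value
  }
  worst <- 0
  for (r1 in 1:8) {
    for (r2 in 1:8) {
      for (a in 0:r1) {
        for (c in 1:r2) {
          got <- enrich_p(a, r1 - a, c, r2 - c)
          want <- oracle_fisher_greater(a, r1 - a, c, r2 - c)
          worst <- max(worst, abs(got - want))
        }
      }
    }
  }
  expect_lt(worst, 1e-9)
})
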