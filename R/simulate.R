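#' Configuration for the synthetic-cohort generator
#'
#' Defaults describe the study conditions the recovery analyses assume: a
#' small carcinoma cohort with deep allelic counts at germline-het SNPs, a
#' two-exon target tumor-suppressor gene hit by truncating variants
#' according to a two-hit scenario mix (4:1:1:4 two-hit : somatic+LOH :
#' germline-only : wild-type), allele-specific expression favouring the
#' somatically mutated copies, and a C>T passenger spectrum with a
#' controllable fraction of mutations at TCW motifs.
#'
#' @param n_samples Samples in the cohort (default 10).
#' @param n_loci Germline-het background SNP loci per sample (default 500).
#' @param depth_dna,depth_rna Mean sequencing depth per locus (default
#'   10000 each; reads are binomial draws at that fixed depth).
#' @param purity_range Tumor purity drawn uniformly from this interval
#'   (default c(0.4, 0.9)).
#' @param segment_cn_menu data.frame `cn_ref, cn_alt, weight`: the
#'   allele-specific copy-number states available to background segments.
#' @param scenario_mix Named probabilities over
#'   `wild_type, germline_only, somatic_LOH, two_hit` (must sum to 1).
#' @param gene_cn_two_hit Copy numbers `(cn_ref, cn_alt)` over the gene in
#'   the two-hit scenario, oriented to the somatic variant (REF-bearing =
#'   the germline-mutant copy); default c(1, 2): gain of the somatic copy.
#' @param ase_factor Expression multiplier on the somatically mutated
#'   copies (default 4, inside the 2.3-7.9 fold range the method is meant
#'   to resolve).
#' @param germline_ase_factor Expression multiplier on the germline-mutant
#'   copy in the germline-only scenario (default 0.3: first-hit
#'   suppression).
#' @param n_passenger_snvs Somatic passenger C>T SNVs per sample
#'   (default 150).
#' @param apobec_fraction Probability that a passenger lands on the C of a
#'   TCW motif rather than uniformly on other cytosines (default 0.6).
#' @param overdispersion Beta-binomial overdispersion rho in \[0, 1);
#'   0 (default) gives plain binomial read sampling.
#' @param n_contigs,contig_length,gc Toy reference genome shape
#'   (default 2 contigs of 50 kb at GC 0.4).
#' @param seed Integer master seed; fixed seed gives byte-identical output.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 10, n_loci = 500,
                       depth_dna = 10000, depth_rna = 10000,
                       purity_range = c(0.4, 0.9),
                       segment_cn_menu = data.frame(
                         cn_ref = c(1, 1, 2, 2, 0),
                         cn_alt = c(1, 2, 1, 2, 1),
                         weight = c(0.4, 0.2, 0.2, 0.1, 0.1)),
                       scenario_mix = c(wild_type = 0.4, germline_only = 0.1,
                                        somatic_LOH = 0.1, two_hit = 0.4),
                       gene_cn_two_hit = c(1, 2),
                       ase_factor = 4,
                       germline_ase_factor = 0.3,
                       n_passenger_snvs = 150,
                       apobec_fraction = 0.6,
                       overdispersion = 0,
                       n_contigs = 2, contig_length = 50000, gc = 0.4,
                       seed = 1L) {
  scen <- c("wild_type", "germline_only", "somatic_LOH", "two_hit")
  if (!setequal(names(scenario_mix), scen)) {
    stop("scenario_mix must name exactly: ", paste(scen, collapse = ", "))
  }
  scenario_mix <- scenario_mix[scen]
  if (abs(sum(scenario_mix) - 1) > 1e-8 || any(scenario_mix < 0)) {
    stop("scenario_mix probabilities must be non-negative and sum to 1")
  }
  if (depth_dna < 1 || depth_rna < 1) stop("depths must be >= 1")
  if (length(purity_range) != 2 || purity_range[1] <= 0 ||
      purity_range[2] > 1 || purity_range[1] > purity_range[2]) {
    stop("purity_range must be an interval within (0, 1]")
  }
  if (any(segment_cn_menu$cn_ref + segment_cn_menu$cn_alt <= 0) ||
      any(segment_cn_menu$weight < 0)) {
    stop("invalid segment_cn_menu")
  }
  if (apobec_fraction < 0 || apobec_fraction > 1) {
    stop("apobec_fraction must lie in [0, 1]")
  }
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("overdispersion must lie in [0, 1)")
  }
  if (ase_factor <= 0 || germline_ase_factor <= 0) {
    stop("expression factors must be positive")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Beta-binomial draws; rho = 0 degenerates to binomial.
.rcounts <- function(n, size, prob, rho = 0) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  nu <- (1 - rho) / rho
  p <- stats::rbeta(n, prob * nu, (1 - prob) * nu)
  stats::rbinom(n, size, p)
}

# Expected RNA ALT fraction when tumor copies carry expression factors:
# each tumor REF copy transcribes at rate f_ref, each ALT copy at f_alt;
# normal copies transcribe at rate 1 (the no-DEG condition).
.rna_expected_vaf <- function(purity, cn_ref, cn_alt, locus_class,
                              f_ref = 1, f_alt = 1) {
  nrm <- .cn_normal(locus_class)
  num <- (1 - purity) * nrm$alt + purity * cn_alt * f_alt
  den <- (1 - purity) * (nrm$ref + nrm$alt) +
    purity * (cn_ref * f_ref + cn_alt * f_alt)
  num / den
}

#' Generate the seeded toy reference genome and target-gene model
#'
#' Builds a random reference (i.i.d. bases at the configured GC content)
#' plus a two-exon target gene on the first contig whose coding intervals
#' receive the scenario variants. Generated, never shipped: the genome is a
#' function of the seed alone.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `gene`
#'   ([gene_model()]), and `sites` (data.frame of cytosine sites on both
#'   strands with their TCW status, used to place passenger mutations).
#' @export
sim_reference <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed %% 2147483647L)
  gc <- config$gc
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(config$n_contigs), function(i) {
    paste(sample(names(probs), config$contig_length, replace = TRUE,
                 prob = probs), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_contigs))
  gene <- gene_model("TSG1", "chr1",
                     starts = c(5001L, 8001L), ends = c(5600L, 9200L))
  list(genome = genome, gene = gene, sites = .cytosine_sites(genome))
}

# All cytosine positions on either strand (reference C or G), excluding
# contig edges, with TCW-motif membership: plus-strand C with 5' T and
# 3' A/T, or reference G inside a WGA motif (the minus-strand TCW).
.cytosine_sites <- function(genome) {
  out <- lapply(names(genome), function(chr) {
    s <- strsplit(as.character(genome[[chr]]), "")[[1]]
    L <- length(s)
    i <- 2:(L - 1)
    base <- s[i]; up <- s[i - 1]; down <- s[i + 1]
    c_plus <- base == "C"
    c_minus <- base == "G"
    keep <- c_plus | c_minus
    data.frame(
      chrom = chr, pos = i[keep], ref = base[keep],
      is_tcw = ifelse(c_plus[keep],
                      up[keep] == "T" & down[keep] %in% c("A", "T"),
                      up[keep] %in% c("A", "T") & down[keep] == "A"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Random segmentation of one contig; `fixed` intervals (start, end) are
# forced to be whole segments (the gene segment).
.segment_contig <- function(chrom, L, fixed = NULL, n_extra = 6) {
  cuts <- sort(sample(seq(1000L, L - 1000L), n_extra))
  bounds <- c(0L, cuts, L)
  if (!is.null(fixed)) {
    bounds <- bounds[bounds <= fixed[1] - 1L | bounds >= fixed[2]]
    bounds <- sort(unique(c(bounds, fixed[1] - 1L, fixed[2])))
  }
  data.frame(chrom = chrom,
             start = bounds[-length(bounds)] + 1L,
             end = bounds[-1])
}

#' Simulate one sample of the synthetic cohort
#'
#' Draws a tumor purity, assigns allele-specific copy-number segments,
#' scatters germline-het SNPs, plants target-gene truncating variants per
#' the drawn two-hit scenario (LOH realised as `cn_ref = 0` over the gene
#' segment), samples DNA and RNA allelic read counts binomially at the
#' admixture-model expectations (RNA rates carry the allele-specific
#' expression factors), and places passenger C>T SNVs at TCW motifs with
#' probability `apobec_fraction`.
#'
#' @param config A [sim_config()].
#' @param sample_index Integer 1..n_samples; also salts the per-sample seed.
#' @param ref Result of [sim_reference()] (rebuilt from `config` if NULL).
#' @return List with `sample_id, purity, scenario, variants, dna_counts,
#'   rna_counts, segments, loci_cn, truth_loci`.
#' @export
simulate_sample <- function(config, sample_index, ref = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(ref)) ref <- sim_reference(config)
  genome <- ref$genome; gene <- ref$gene
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed((config$seed * 1000L + sample_index) %% 2147483647L)

  sample_id <- sprintf("S%02d", sample_index)
  purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
  scenario <- sample(names(config$scenario_mix), 1,
                     prob = config$scenario_mix)
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  gene_span <- c(min(gene$starts), max(gene$ends))

  # --- segments ------------------------------------------------------------
  seg_list <- lapply(names(genome), function(chr) {
    if (chr == gene$chrom) {
      .segment_contig(chr, chrlen[[chr]],
                      fixed = c(gene_span[1] - 500L, gene_span[2] + 500L))
    } else .segment_contig(chr, chrlen[[chr]])
  })
  segments <- do.call(rbind, seg_list)
  menu <- config$segment_cn_menu
  pick <- sample(nrow(menu), nrow(segments), replace = TRUE,
                 prob = menu$weight)
  segments$cn_ref_tumor <- menu$cn_ref[pick]
  segments$cn_alt_tumor <- menu$cn_alt[pick]
  gene_seg <- which(segments$chrom == gene$chrom &
                      segments$start <= gene_span[1] &
                      segments$end >= gene_span[2])
  stopifnot(length(gene_seg) == 1)
  # Gene-segment CN oriented to the somatic variant (REF = germline copy).
  gene_cn <- switch(scenario,
                    two_hit = config$gene_cn_two_hit,
                    somatic_LOH = c(0, 1),
                    germline_only = c(1, 1),
                    wild_type = c(segments$cn_ref_tumor[gene_seg],
                                  segments$cn_alt_tumor[gene_seg]))
  segments$cn_ref_tumor[gene_seg] <- gene_cn[1]
  segments$cn_alt_tumor[gene_seg] <- gene_cn[2]

  # --- gene scenario variants ---------------------------------------------
  genome_chr <- lapply(as.character(genome), identity)
  names(genome_chr) <- names(genome)
  gene_variants <- NULL
  loci_cn <- NULL
  # positions inside coding intervals: somatic hit in exon 1, germline in 2
  som_pos <- sample(seq(gene$starts[1] + 1L, gene$ends[1] - 2L), 1)
  germ_pos <- sample(seq(gene$starts[2] + 1L, gene$ends[2] - 2L), 1)
  base_at <- function(chr, p, n = 1) substr(genome_chr[[chr]], p, p + n - 1L)
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  add_gene_variant <- function(pos, origin, effect, cn, f_ref, f_alt,
                               locus_class) {
    if (effect == "frameshift_indel") {
      refb <- base_at(gene$chrom, pos, 2); altb <- substr(refb, 1, 1)
    } else {
      refb <- base_at(gene$chrom, pos); altb <- other_base(refb)
    }
    data.frame(chrom = gene$chrom, pos = pos, ref = refb, alt = altb,
               origin = origin, effect = effect, gene_id = gene$gene_id,
               locus_class = locus_class,
               cn_ref = cn[1], cn_alt = cn[2],
               f_ref = f_ref, f_alt = f_alt,
               role = paste0(origin, "_hit"),
               stringsAsFactors = FALSE)
  }
  f <- config$ase_factor
  if (scenario == "two_hit") {
    gene_variants <- rbind(
      # germline hit: ALT copy = germline haplotype (cn orientation swapped);
      # the REF copies at this locus are the somatic haplotype (factor f)
      add_gene_variant(germ_pos, "germline", "frameshift_indel",
                       cn = c(gene_cn[2], gene_cn[1]),
                       f_ref = f, f_alt = 1, locus_class = "germline_het"),
      add_gene_variant(som_pos, "somatic", "nonsense",
                       cn = gene_cn, f_ref = 1, f_alt = f,
                       locus_class = "somatic"))
  } else if (scenario == "somatic_LOH") {
    gene_variants <- add_gene_variant(som_pos, "somatic", "frameshift_indel",
                                      cn = gene_cn, f_ref = 1, f_alt = f,
                                      locus_class = "somatic")
  } else if (scenario == "germline_only") {
    gene_variants <- add_gene_variant(germ_pos, "germline",
                                      "frameshift_indel",
                                      cn = c(gene_cn[2], gene_cn[1]),
                                      f_ref = 1,
                                      f_alt = config$germline_ase_factor,
                                      locus_class = "germline_het")
  }
  if (!is.null(gene_variants)) {
    loci_cn <- data.frame(
      locus_id = paste0(gene_variants$chrom, ":", gene_variants$pos),
      chrom = gene_variants$chrom, pos = gene_variants$pos,
      cn_ref_tumor = gene_variants$cn_ref,
      cn_alt_tumor = gene_variants$cn_alt, stringsAsFactors = FALSE)
  }

  # --- background germline-het SNPs ---------------------------------------
  taken <- if (is.null(gene_variants)) integer(0) else gene_variants$pos
  bg <- do.call(rbind, lapply(names(genome), function(chr) {
    n_chr <- round(config$n_loci * chrlen[[chr]] / sum(chrlen))
    pos <- sort(sample(seq(3L, chrlen[[chr]] - 3L), n_chr))
    if (chr == gene$chrom) pos <- setdiff(pos, c(taken, taken + 1L))
    data.frame(chrom = chr, pos = pos, stringsAsFactors = FALSE)
  }))
  bg$ref <- vapply(seq_len(nrow(bg)),
                   function(i) base_at(bg$chrom[i], bg$pos[i]), character(1))
  bg$alt <- vapply(bg$ref, other_base, character(1))
  seg_idx <- .match_segment_index(bg$chrom, bg$pos, segments)
  bg$cn_ref <- segments$cn_ref_tumor[seg_idx]
  bg$cn_alt <- segments$cn_alt_tumor[seg_idx]
  bg$origin <- "germline"; bg$effect <- "noncoding"
  bg$gene_id <- NA_character_; bg$locus_class <- "germline_het"
  bg$f_ref <- 1; bg$f_alt <- 1; bg$role <- "background"

  # --- passenger somatic C>T SNVs -----------------------------------------
  sites <- ref$sites
  used <- paste0(c(bg$chrom, gene_variants$chrom),
                 ":", c(bg$pos, gene_variants$pos))
  sites <- sites[!paste0(sites$chrom, ":", sites$pos) %in% used, ]
  n_pass <- config$n_passenger_snvs
  at_tcw <- stats::rbinom(n_pass, 1, config$apobec_fraction) == 1
  tcw_pool <- which(sites$is_tcw); other_pool <- which(!sites$is_tcw)
  idx <- integer(n_pass)
  idx[at_tcw] <- sample(tcw_pool, sum(at_tcw))
  idx[!at_tcw] <- sample(other_pool, sum(!at_tcw))
  pass <- sites[idx, c("chrom", "pos", "ref")]
  pass$alt <- ifelse(pass$ref == "C", "T", "A")  # C>T (minus strand: G>A)
  seg_idx <- .match_segment_index(pass$chrom, pass$pos, segments)
  tot_cn <- segments$cn_ref_tumor[seg_idx] + segments$cn_alt_tumor[seg_idx]
  pass$cn_ref <- pmax(tot_cn - 1, 0); pass$cn_alt <- 1
  pass$origin <- "somatic"; pass$effect <- "noncoding"
  pass$gene_id <- NA_character_; pass$locus_class <- "somatic"
  pass$f_ref <- 1; pass$f_alt <- 1; pass$role <- "passenger"
  pass$is_tcw_truth <- sites$is_tcw[idx]

  # --- assemble loci and draw reads ---------------------------------------
  cols <- c("chrom", "pos", "ref", "alt", "origin", "effect", "gene_id",
            "locus_class", "cn_ref", "cn_alt", "f_ref", "f_alt", "role")
  loci <- rbind(bg[, cols],
                if (!is.null(gene_variants)) gene_variants[, cols],
                pass[, cols])
  loci <- loci[order(match(loci$chrom, names(genome)), loci$pos), ]
  rownames(loci) <- NULL
  loci$locus_id <- paste0(loci$chrom, ":", loci$pos)

  exp_vaf <- expected_observed_vaf(purity, loci$cn_ref, loci$cn_alt,
                                   loci$locus_class)
  rho <- config$overdispersion
  alt_dna <- .rcounts(nrow(loci), config$depth_dna, exp_vaf, rho)
  germ <- loci$origin == "germline"
  alt_norm <- ifelse(germ,
                     .rcounts(nrow(loci), config$depth_dna, 0.5, rho), 0L)
  dna_counts <- data.frame(
    locus_id = rep(loci$locus_id, 2),
    assay = rep(c("normal_dna", "tumor_dna"), each = nrow(loci)),
    ref_count = c(config$depth_dna - alt_norm, config$depth_dna - alt_dna),
    alt_count = c(alt_norm, alt_dna), stringsAsFactors = FALSE)

  # RNA at germline-het SNPs and gene hit loci (passengers are not
  # transcribed in this toy model)
  rna_idx <- which(loci$role != "passenger")
  rna_exp <- .rna_expected_vaf(purity, loci$cn_ref[rna_idx],
                               loci$cn_alt[rna_idx],
                               loci$locus_class[rna_idx],
                               loci$f_ref[rna_idx], loci$f_alt[rna_idx])
  alt_rna <- .rcounts(length(rna_idx), config$depth_rna, rna_exp, rho)
  rna_counts <- data.frame(
    locus_id = loci$locus_id[rna_idx],
    chrom = loci$chrom[rna_idx], pos = loci$pos[rna_idx],
    ref_count = config$depth_rna - alt_rna, alt_count = alt_rna,
    stringsAsFactors = FALSE)

  truth_loci <- data.frame(
    locus_id = loci$locus_id, chrom = loci$chrom, pos = loci$pos,
    locus_class = loci$locus_class, role = loci$role,
    cn_ref = loci$cn_ref, cn_alt = loci$cn_alt,
    copy_fraction = loci$cn_alt / (loci$cn_ref + loci$cn_alt),
    expected_vaf = exp_vaf,
    ase_fold_true = loci$f_alt / loci$f_ref, stringsAsFactors = FALSE)

  list(sample_id = sample_id, purity = purity, scenario = scenario,
       variants = loci, dna_counts = dna_counts, rna_counts = rna_counts,
       segments = segments, loci_cn = loci_cn, truth_loci = truth_loci)
}

# Segment index covering each locus (segments non-overlapping, sorted).
.match_segment_index <- function(chrom, pos, segments) {
  idx <- rep(NA_integer_, length(pos))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    seg <- which(segments$chrom == chr)
    if (length(seg) == 0) next
    w <- which(sel)
    j <- findInterval(pos[w], segments$start[seg])
    ok <- j >= 1 & j <= length(seg)
    ok[ok] <- pos[w][ok] <= segments$end[seg][j[ok]]
    idx[w[ok]] <- seg[j[ok]]
  }
  idx
}

#' Simulate and write a full synthetic cohort
#'
#' Runs [simulate_sample()] for each sample and writes one file set per
#' sample — a VCF v4.2 with per-sample AD for normal and tumor DNA, an
#' allele-specific copy-number segment table, a tumor-RNA allelic-count
#' table and a per-locus CN override table for the target-gene loci — plus
#' the shared reference FASTA, the gene model, a cohort manifest and a
#' ground-truth JSON. Output is byte-identical for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, a list with the manifest data.frame, file `paths`,
#'   and the in-memory `samples`.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  ref <- sim_reference(config)
  fa <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(ref$genome, fa)
  gm <- file.path(out_dir, "gene_model.tsv")
  utils::write.table(
    data.frame(gene_id = ref$gene$gene_id, chrom = ref$gene$chrom,
               start = ref$gene$starts, end = ref$gene$ends,
               strand = ref$gene$strand),
    gm, sep = "\t", quote = FALSE, row.names = FALSE)

  samples <- lapply(seq_len(config$n_samples), function(i)
    simulate_sample(config, i, ref))
  manifest <- do.call(rbind, lapply(samples, function(s) {
    vcf <- file.path(out_dir, paste0(s$sample_id, ".vcf"))
    .write_allelic_vcf(s, ref$genome, vcf)
    seg <- file.path(out_dir, paste0(s$sample_id, "_segments.tsv"))
    utils::write.table(s$segments, seg, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rna <- file.path(out_dir, paste0(s$sample_id, "_rna_counts.tsv"))
    utils::write.table(s$rna_counts, rna, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lcn <- ""
    if (!is.null(s$loci_cn)) {
      lcn <- file.path(out_dir, paste0(s$sample_id, "_loci_cn.tsv"))
      utils::write.table(s$loci_cn, lcn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    data.frame(sample_id = s$sample_id, purity = s$purity,
               vcf = basename(vcf), segments = basename(seg),
               rna_counts = basename(rna),
               loci_cn = ifelse(lcn == "", "", basename(lcn)),
               stringsAsFactors = FALSE)
  }))
  mf <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    seed = config$seed,
    scenario_mix = as.list(config$scenario_mix),
    ase_factor = config$ase_factor,
    germline_ase_factor = config$germline_ase_factor,
    apobec_fraction = config$apobec_fraction,
    samples = lapply(samples, function(s)
      list(sample_id = s$sample_id, purity = s$purity,
           scenario = s$scenario, loci = s$truth_loci)))
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(manifest = manifest,
                 paths = list(dir = out_dir, reference = fa, gene_model = gm,
                              manifest = mf, truth = tj),
                 samples = samples))
}

# Minimal VCF v4.2 emitter: one file per sample, NORMAL/TUMOR columns with
# AD:DP, variant annotations in INFO.
.write_allelic_vcf <- function(s, genome, path) {
  loci <- s$variants
  dn <- s$dna_counts
  nrm <- dn[dn$assay == "normal_dna", ]
  tum <- dn[dn$assay == "tumor_dna", ]
  nrm <- nrm[match(loci$locus_id, nrm$locus_id), ]
  tum <- tum[match(loci$locus_id, tum$locus_id), ]
  info <- paste0("ORIGIN=", toupper(loci$origin),
                 ";EFFECT=", loci$effect,
                 ";CLASS=", loci$locus_class,
                 ifelse(is.na(loci$gene_id), "",
                        paste0(";GENE=", loci$gene_id)))
  fmt <- function(d) paste0(d$ref_count, ",", d$alt_count, ":",
                            d$ref_count + d$alt_count)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(genome), ",length=",
           Biostrings::width(genome), ">"),
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Variant origin: GERMLINE or SOMATIC\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Annotated coding effect\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Locus class: germline_het or somatic\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene containing the variant\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "TUMOR", sep = "\t"))
  body <- paste(loci$chrom, loci$pos, loci$locus_id, loci$ref, loci$alt,
                ".", "PASS", info, "AD:DP", fmt(nrm), fmt(tum), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
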