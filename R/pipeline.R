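#' Read a VCF of allelic counts into a locus table
#'
#' Parses a VCF v4.2 with per-sample `AD` (allelic depth) FORMAT fields
#' into a flat data.frame, carrying the `ORIGIN`, `EFFECT`, `CLASS` and
#' `GENE` INFO annotations used downstream. Multi-allelic records are
#' rejected: allele-specific deconvolution is defined for one ALT allele
#' per record (split multi-allelics upstream, e.g. `bcftools norm -m-`).
#'
#' @param path VCF file (plain or bgzipped).
#' @param normal_col,tumor_col Sample-column names holding the normal-DNA
#'   and tumor-DNA allelic depths.
#' @return data.frame: `locus_id, chrom, pos, ref, alt, origin, effect,
#'   locus_class, gene_id, normal_ref, normal_alt, tumor_ref, tumor_alt`.
#' @export
read_allelic_vcf <- function(path, normal_col = "NORMAL",
                             tumor_col = "TUMOR") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) {  # single-record VCF: vcfR drops the dimension
    fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  }
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    bad <- which(grepl(",", fix$ALT, fixed = TRUE))[1]
    stop("multi-allelic record at ", fix$CHROM[bad], ":", fix$POS[bad],
         " in ", path, "; split records before deconvolution")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  for (col in c(normal_col, tumor_col)) {
    if (!col %in% colnames(ad)) {
      stop("sample column '", col, "' not found in ", path)
    }
  }
  split_ad <- function(x) {
    m <- do.call(rbind, strsplit(x, ",", fixed = TRUE))
    matrix(as.integer(m), ncol = 2)
  }
  adn <- split_ad(ad[, normal_col]); adt <- split_ad(ad[, tumor_col])
  grab <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    ifelse(is.na(x), NA_character_, x)
  }
  data.frame(
    locus_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    origin = tolower(grab("ORIGIN")), effect = grab("EFFECT"),
    locus_class = grab("CLASS"), gene_id = grab("GENE"),
    normal_ref = adn[, 1], normal_alt = adn[, 2],
    tumor_ref = adt[, 1], tumor_alt = adt[, 2],
    stringsAsFactors = FALSE)
}

#' Read an allele-specific copy-number segment table
#'
#' Tab-delimited with header `chrom, start, end, cn_ref_tumor,
#' cn_alt_tumor`; 1-based inclusive coordinates. Validates that segments
#' are sorted and non-overlapping within each chromosome.
#'
#' @param path File path.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "cn_ref_tumor", "cn_alt_tumor")
  if (!all(need %in% names(seg))) {
    stop("segment file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      i <- which(s$start[-1] <= s$end[-nrow(s)])[1]
      stop("overlapping segments in ", path, ": ", chr, ":", s$start[i],
           "-", s$end[i], " and ", chr, ":", s$start[i + 1], "-",
           s$end[i + 1])
    }
  }
  seg[order(match(seg$chrom, unique(seg$chrom)), seg$start), ]
}

#' Match loci to their covering copy-number segment
#'
#' Binary-search lookup (1-based inclusive interval test) of each locus in
#' a sorted, non-overlapping segment table. A locus on a segment boundary
#' is covered; a locus outside every segment gets `NA` copy numbers and is
#' expected to be skipped (with a logged reason) by callers.
#'
#' @param chrom,pos Locus coordinate vectors.
#' @param segments Segment data.frame as from [read_segments()].
#' @return data.frame `cn_ref_tumor, cn_alt_tumor, segment` (row index into
#'   `segments`, NA when uncovered).
#' @export
match_locus_to_segment <- function(chrom, pos, segments) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      i <- which(s$start[-1] <= s$end[-nrow(s)])[1]
      stop("overlapping segments cover the same loci: ", chr, ":",
           s$start[i], "-", s$end[i], " and ", chr, ":", s$start[i + 1],
           "-", s$end[i + 1])
    }
  }
  idx <- .match_segment_index(chrom, pos, segments)
  data.frame(cn_ref_tumor = segments$cn_ref_tumor[idx],
             cn_alt_tumor = segments$cn_alt_tumor[idx],
             segment = idx)
}

#' Run the allelic-imbalance pipeline on a cohort directory
#'
#' End-to-end orchestration over a cohort laid out as [simulate_cohort()]
#' writes it (and as real data can be arranged): a `manifest.tsv` naming
#' per-sample VCF, segment, RNA-count and optional per-locus CN files, a
#' shared reference FASTA and a target-gene model. Stages per sample:
#' \enumerate{
#'   \item match every VCF locus to its copy-number segment (per-locus CN
#'     overrides take precedence — they carry the REF/ALT-to-haplotype
#'     phase that a segment-level major/minor pair cannot);
#'   \item deconvolute tumor-DNA allelic counts to intratumor VAFs;
#'   \item compute allele-specific expression folds at target-gene loci
#'     from the RNA counts (skipped with a note when RNA is absent or the
#'     fold is undefined, e.g. complete REF loss);
#'   \item classify the sample's two-hit inactivation state;
#'   \item build the 96-class trinucleotide matrix over somatic SNVs
#'     (observed VAF strictly greater than `vaf_filter`) and compute the
#'     APOBEC tCw enrichment score with its one-sided Fisher test.
#' }
#' Every input locus lands either in an output table or in the skip log
#' with a reason. Results are written as tab-delimited tables plus a run
#' log; reruns with identical inputs and options are byte-identical.
#'
#' @param cohort_dir Directory containing `manifest.tsv`, `reference.fa`,
#'   `gene_model.tsv` and the per-sample files.
#' @param out_dir Output directory (created).
#' @param target_gene Gene id for the ASE and two-hit stages.
#' @param vaf_filter Somatic observed-VAF filter for the mutation matrix.
#' @param window Background half-window (bp) for APOBEC context counting.
#' @param mutation_classes Substitution classes for the APOBEC statistic.
#' @param gene_is_deg,proportional_expression_assumed RNA-applicability
#'   inputs for [ase_eligibility()] (DEG status is computed outside this
#'   package).
#' @param verbose Print per-sample progress to stderr.
#' @return Invisibly, list with `vaf` (per-locus deconvolution table),
#'   `ase`, `genotypes`, `apobec`, `summary` data.frames and `skipped`.
#' @export
run_pipeline <- function(cohort_dir, out_dir,
                         target_gene = "TSG1",
                         vaf_filter = 0.05, window = 20,
                         mutation_classes = "C>T",
                         gene_is_deg = FALSE,
                         proportional_expression_assumed = TRUE,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  mf_path <- file.path(cohort_dir, "manifest.tsv")
  for (p in c(mf_path, file.path(cohort_dir, "reference.fa"),
              file.path(cohort_dir, "gene_model.tsv"))) {
    if (!file.exists(p)) stop("missing required input: ", p)
  }
  manifest <- utils::read.delim(mf_path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(manifest$sample_id))
  genome <- Biostrings::readDNAStringSet(
    file.path(cohort_dir, "reference.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  gene <- read_gene_model(file.path(cohort_dir, "gene_model.tsv"),
                          target_gene)
  eligible <- ase_eligibility(gene_is_deg, proportional_expression_assumed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  vaf_all <- list(); ase_all <- list(); geno_all <- list()
  apo_all <- list(); skip_all <- list(); summ_all <- list()
  for (k in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[k]
    purity <- manifest$purity[k]
    say("sample ", sid, " (purity ", signif(purity, 3), ")")
    loci <- read_allelic_vcf(file.path(cohort_dir, manifest$vcf[k]))
    segments <- read_segments(file.path(cohort_dir, manifest$segments[k]))
    skip <- data.frame(sample_id = character(0), locus_id = character(0),
                       stage = character(0), reason = character(0))
    note_skip <- function(ids, stage, reason) {
      if (length(ids) == 0) return(skip)
      rbind(skip, data.frame(sample_id = sid, locus_id = ids,
                             stage = stage, reason = reason))
    }

    cn <- match_locus_to_segment(loci$chrom, loci$pos, segments)
    if (!is.null(manifest$loci_cn) && !is.na(manifest$loci_cn[k]) &&
        nzchar(manifest$loci_cn[k])) {
      over <- utils::read.delim(file.path(cohort_dir, manifest$loci_cn[k]),
                                stringsAsFactors = FALSE)
      m <- match(loci$locus_id, over$locus_id)
      cn$cn_ref_tumor[!is.na(m)] <- over$cn_ref_tumor[m[!is.na(m)]]
      cn$cn_alt_tumor[!is.na(m)] <- over$cn_alt_tumor[m[!is.na(m)]]
    }

    uncov <- is.na(cn$cn_ref_tumor)
    skip <- note_skip(loci$locus_id[uncov], "deconvolution",
                      "no covering copy-number segment")
    depth0 <- loci$tumor_ref + loci$tumor_alt == 0
    skip <- note_skip(loci$locus_id[depth0 & !uncov], "deconvolution",
                      "zero tumor-DNA depth")
    use <- !uncov & !depth0
    dec <- deconvolve_counts(loci$tumor_ref[use], loci$tumor_alt[use],
                             purity, cn$cn_ref_tumor[use],
                             cn$cn_alt_tumor[use], loci$locus_class[use])
    vaf_tab <- data.frame(
      sample_id = sid, locus_id = loci$locus_id[use],
      assay = "tumor_dna",
      origin = loci$origin[use], locus_class = loci$locus_class[use],
      cn_ref_tumor = cn$cn_ref_tumor[use],
      cn_alt_tumor = cn$cn_alt_tumor[use],
      observed_vaf = loci$tumor_alt[use] /
        (loci$tumor_ref[use] + loci$tumor_alt[use]),
      ref_tumor = dec$ref_tumor, alt_tumor = dec$alt_tumor,
      vaf_tumor = dec$vaf_tumor, stringsAsFactors = FALSE)
    vaf_all[[sid]] <- vaf_tab

    # --- allele-specific expression at target-gene loci -------------------
    gene_loci <- which(!is.na(loci$gene_id) & loci$gene_id == target_gene)
    has_rna <- !is.null(manifest$rna_counts) &&
      !is.na(manifest$rna_counts[k]) && nzchar(manifest$rna_counts[k])
    if (has_rna && length(gene_loci) > 0) {
      rna <- utils::read.delim(
        file.path(cohort_dir, manifest$rna_counts[k]),
        stringsAsFactors = FALSE)
      ase_rows <- lapply(gene_loci, function(i) {
        r <- rna[rna$locus_id == loci$locus_id[i], ]
        base <- data.frame(sample_id = sid, locus_id = loci$locus_id[i],
                           origin = loci$origin[i],
                           fold = NA_real_, rna_vaf_tumor = NA_real_,
                           dna_copy_fraction = NA_real_,
                           eligible = eligible, note = "",
                           stringsAsFactors = FALSE)
        if (nrow(r) == 0 || r$ref_count + r$alt_count == 0) {
          base$note <- "no RNA coverage"
          return(base)
        }
        if (is.na(cn$cn_ref_tumor[i])) {
          base$note <- "no covering copy-number segment"
          return(base)
        }
        res <- tryCatch(
          withCallingHandlers(
            ase_fold(r$ref_count, r$alt_count, purity,
                     cn$cn_ref_tumor[i], cn$cn_alt_tumor[i],
                     loci$locus_class[i], eligible = eligible),
            warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) conditionMessage(e))
        if (is.character(res)) {
          base$note <- res
          return(base)
        }
        base$fold <- res$fold
        base$rna_vaf_tumor <- res$rna_vaf_tumor
        base$dna_copy_fraction <- res$dna_copy_fraction
        base
      })
      ase_all[[sid]] <- do.call(rbind, ase_rows)
    } else if (length(gene_loci) > 0) {
      ase_all[[sid]] <- data.frame(
        sample_id = sid, locus_id = loci$locus_id[gene_loci],
        origin = loci$origin[gene_loci], fold = NA_real_,
        rna_vaf_tumor = NA_real_, dna_copy_fraction = NA_real_,
        eligible = eligible, note = "no RNA data for sample",
        stringsAsFactors = FALSE)
    }

    # --- two-hit genotype --------------------------------------------------
    gv <- loci[gene_loci, , drop = FALSE]
    variants <- data.frame(variant_id = gv$locus_id, chrom = gv$chrom,
                           pos = gv$pos, ref = gv$ref, alt = gv$alt,
                           origin = gv$origin, effect = gv$effect,
                           stringsAsFactors = FALSE)
    # CN oriented to the somatic variant decides LOH; fall back to the
    # segment covering the gene when no somatic variant is present.
    som <- which(gv$origin == "somatic")
    if (length(som) > 0) {
      cn_gene_ref <- cn$cn_ref_tumor[gene_loci[som[1]]]
      cn_gene_alt <- cn$cn_alt_tumor[gene_loci[som[1]]]
    } else {
      at_gene <- match_locus_to_segment(gene$chrom, gene$starts[1],
                                        segments)
      cn_gene_ref <- at_gene$cn_ref_tumor; cn_gene_alt <- at_gene$cn_alt_tumor
    }
    geno_all[[sid]] <- classify_sample_genotype(
      variants, gene, cn_ref_tumor = cn_gene_ref,
      cn_alt_tumor = cn_gene_alt, sample_id = sid)

    # --- APOBEC enrichment -------------------------------------------------
    is_som_snv <- loci$origin == "somatic" &
      nchar(loci$ref) == 1 & nchar(loci$alt) == 1
    apo_row <- data.frame(sample_id = sid, score = NA_real_,
                          n_tCw = NA_integer_, n_C = NA_integer_,
                          background_TCW = NA_integer_,
                          background_C = NA_integer_, p_value = NA_real_,
                          n_snvs_used = 0L,
                          mutation_classes = paste(mutation_classes,
                                                   collapse = ","),
                          note = "", stringsAsFactors = FALSE)
    if (any(is_som_snv)) {
      snvs <- data.frame(
        sample_id = sid, chrom = loci$chrom[is_som_snv],
        pos = loci$pos[is_som_snv], ref = loci$ref[is_som_snv],
        alt = loci$alt[is_som_snv],
        vaf = loci$tumor_alt[is_som_snv] /
          pmax(loci$tumor_ref[is_som_snv] + loci$tumor_alt[is_som_snv], 1),
        stringsAsFactors = FALSE)
      tm <- build_trinucleotide_matrix(snvs, genome,
                                       vaf_filter = vaf_filter)
      if (nrow(tm$skipped) > 0) {
        skip <- note_skip(paste0(tm$skipped$chrom, ":", tm$skipped$pos),
                          "trinucleotide_matrix", tm$skipped$reason)
      }
      retained <- snvs[snvs$vaf > vaf_filter, c("chrom", "pos")]
      if (tm$n_total[sid] > 0) {
        bg <- count_background_contexts(genome, retained, window = window)
        enr <- tryCatch(
          apobec_enrichment(tm, bg, mutation_classes = mutation_classes,
                            sample = sid),
          error = function(e) conditionMessage(e))
        if (is.character(enr)) {
          apo_row$note <- enr
        } else {
          apo_row$score <- enr$score
          apo_row$n_tCw <- enr$n_tCw; apo_row$n_C <- enr$n_C
          apo_row$background_TCW <- enr$background_TCW
          apo_row$background_C <- enr$background_C
          apo_row$p_value <- enr$p_value
          apo_row$n_snvs_used <- as.integer(tm$n_total[sid])
        }
      } else apo_row$note <- "no somatic SNVs pass the VAF filter"
    } else apo_row$note <- "no somatic SNVs"
    apo_all[[sid]] <- apo_row
    skip_all[[sid]] <- skip

    som_folds <- if (!is.null(ase_all[[sid]])) {
      f <- ase_all[[sid]]
      f$fold[f$origin == "somatic" & !is.na(f$fold)]
    } else numeric(0)
    summ_all[[sid]] <- data.frame(
      sample_id = sid, purity = purity,
      status = geno_all[[sid]]$status, mut_flag = geno_all[[sid]]$mut_flag,
      n_loci_deconvoluted = sum(use), n_loci_skipped = sum(!use),
      ase_fold_somatic = if (length(som_folds)) som_folds[1] else NA_real_,
      apobec_score = apo_row$score, apobec_p = apo_row$p_value,
      stringsAsFactors = FALSE)
  }

  out <- list(vaf = do.call(rbind, c(vaf_all, make.row.names = FALSE)),
              ase = if (length(ase_all))
                do.call(rbind, c(ase_all, make.row.names = FALSE)) else NULL,
              genotypes = do.call(rbind, c(geno_all,
                                           make.row.names = FALSE)),
              apobec = do.call(rbind, c(apo_all, make.row.names = FALSE)),
              summary = do.call(rbind, c(summ_all, make.row.names = FALSE)),
              skipped = do.call(rbind, c(skip_all, make.row.names = FALSE)))
  wr <- function(d, f) if (!is.null(d) && nrow(d) > 0)
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(out$vaf, "vaf_tumor.tsv")
  wr(out$ase, "ase.tsv")
  wr(out$genotypes, "genotypes.tsv")
  wr(out$apobec, "apobec.tsv")
  wr(out$summary, "summary.tsv")
  wr(out$skipped, "skipped_loci.tsv")
  writeLines(c(
    paste0("intravaf ", as.character(utils::packageVersion("intravaf"))),
    paste0("cohort_dir: ", cohort_dir),
    paste0("target_gene: ", target_gene),
    paste0("vaf_filter: ", vaf_filter),
    paste0("window: ", window),
    paste0("mutation_classes: ", paste(mutation_classes, collapse = ",")),
    paste0("ase_eligible: ", eligible),
    paste0("samples: ", nrow(manifest)),
    paste0("loci_skipped: ", if (is.null(out$skipped)) 0
           else nrow(out$skipped))),
    file.path(out_dir, "run_log.txt"))
  invisible(out)
}
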