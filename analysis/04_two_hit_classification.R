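#!/usr/bin/env Rscript
# Stage 4 — two-hit inactivation classification.
#
# Checks the per-sample inactivation calls (two_hit, somatic_only_LOH,
# germline_only, wild_type, plus the binary mutant flag) against the
# simulator's generating scenarios; with noise-free copy number, recovery
# should be exact.

suppressPackageStartupMessages(library(intravaf))
library(jsonlite)

cohort_dir <- "scratch/analysis/cohort"
out_dir <- "scratch/analysis/pipeline_out"
if (!dir.exists(out_dir)) stop("run analysis/02_deconvolve_vaf.R first")

geno <- read.delim(file.path(out_dir, "genotypes.tsv"),
                   stringsAsFactors = FALSE)
truth <- read_json(file.path(cohort_dir, "truth.json"),
                   simplifyVector = TRUE)
scen <- data.frame(sample_id = truth$samples$sample_id,
                   scenario = truth$samples$scenario)
expected_status <- c(wild_type = "wild_type",
                     germline_only = "germline_only",
                     somatic_LOH = "somatic_only_LOH",
                     two_hit = "two_hit")
geno <- merge(geno, scen, by = "sample_id")
geno$expected <- unname(expected_status[geno$scenario])
geno$correct <- geno$status == geno$expected
write.table(geno, "results/04_two_hit_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(geno[, c("sample_id", "scenario", "status", "mut_flag", "evidence")],
      row.names = FALSE)
cat(sprintf("Scenario recovery: %d/%d correct (%.0f%%)\n",
            sum(geno$correct), nrow(geno),
            100 * mean(geno$correct)))
cat("Table written to results/04_two_hit_calls.tsv\n")
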