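#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the synthetic carcinoma cohort at the default study conditions
# (10 samples, 500 germline-het loci each, DNA/RNA depth 10,000, two-hit
# scenario mix 4:1:1:4, ASE factor 4, APOBEC fraction 0.6) with ground
# truth. Raw per-sample files (VCF, segments, RNA counts, truth JSON) go
# under scratch/analysis/cohort; a small cohort overview table goes under
# results/.

suppressPackageStartupMessages(library(intravaf))

cohort_dir <- "scratch/analysis/cohort"
dir.create("results", showWarnings = FALSE)
unlink(cohort_dir, recursive = TRUE)

cfg <- sim_config(seed = 1)
co <- simulate_cohort(cfg, cohort_dir)

overview <- do.call(rbind, lapply(co$samples, function(s) {
  data.frame(sample_id = s$sample_id,
             purity = round(s$purity, 3),
             scenario = s$scenario,
             n_loci = nrow(s$truth_loci),
             n_germline_het = sum(s$truth_loci$role == "background"),
             n_somatic_snvs = sum(s$truth_loci$role %in%
                                    c("passenger", "somatic_hit")))
}))
write.table(overview, "results/01_cohort_overview.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(overview), "samples into", cohort_dir, "\n")
print(table(overview$scenario))
cat("Purity range:", paste(range(overview$purity), collapse = " - "), "\n")
cat("Overview written to results/01_cohort_overview.tsv\n")
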