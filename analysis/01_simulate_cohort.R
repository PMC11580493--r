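#!/usr/bin/env Rscript
# Stage 1: build the 5.5 Mbp HG19 bin grid, annotate it, and simulate a
# study-style cfDNA cohort (6 copy-neutral controls + 6 tumor/normal
# mixtures across the diagnostic templates). Writes the grid, per-sample
# count TSVs and the ground-truth table under results/.

suppressPackageStartupMessages(library(csfscna))
seed <- 20260921L
out <- "results"
dir.create(file.path(out, "counts"), recursive = TRUE, showWarnings = FALSE)

grid <- build_bin_grid(hg19_chrom_sizes())
grid <- annotate_synthetic(grid, seed = derive_seed(seed, 1))
write_bin_grid(grid, file.path(out, "bins.tsv"))
cat(sprintf("grid: %d bins, %d usable (%d usable autosomal)\n",
            nrow(grid), sum(grid$usable), sum(grid$usable & is_autosome(grid))))

specs <- study_cohort_specs(master_seed = derive_seed(seed, 2))
cohort <- simulate_cohort(specs, grid)
for (id in names(cohort$samples))
  write_counts(cohort$samples[[id]]$counts, grid,
               file.path(out, "counts", paste0(id, ".tsv")))
utils::write.table(cohort$truth, file.path(out, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d samples (%d controls, %d tumors), ~%.1fM read pairs each\n",
            nrow(cohort$truth), sum(cohort$truth$template == "neutral"),
            sum(cohort$truth$template != "neutral"),
            mean(vapply(cohort$samples, function(s) sum(s$counts$counts), numeric(1))) / 1e6))
cat("wrote results/bins.tsv, results/truth.tsv, results/counts/*.tsv\n")
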