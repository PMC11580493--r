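#!/usr/bin/env Rscript
# Stage 2: score every simulated sample. Reads the grid and count TSVs from
# stage 1, runs GC/mappability correction, median normalization, log2
# transform, +/-0.1 aberration calling and the three diagnostic metrics
# (CNI score, aberrant-bin count with the >=5-bin positivity rule,
# tumor-cfDNA fraction score), plus arm-level calls and diagnostic flags.
# Writes per-sample metrics JSON, log2 bedGraph and call BED files.

suppressPackageStartupMessages(library(csfscna))
out <- "results"
grid <- read_bin_grid(file.path(out, "bins.tsv"))
truth <- utils::read.table(file.path(out, "truth.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
dir.create(file.path(out, "profiles"), showWarnings = FALSE)
dir.create(file.path(out, "metrics"), showWarnings = FALSE)

config <- pipeline_config()
arms <- hg19_arm_table()
regions <- cdkn2ab_region()

counts <- lapply(truth$sample, function(id)
  read_counts(file.path(out, "counts", paste0(id, ".tsv")), grid, sample_id = id))
names(counts) <- truth$sample
groups <- stats::setNames(ifelse(truth$template == "neutral", "control", "tumor"),
                          truth$sample)

report <- run_pipeline(counts, grid, config, groups = groups,
                       arm_table = arms, regions = regions)
for (id in truth$sample) {
  res <- report$samples[[id]]
  write_bedgraph(profile_track(res$profile, grid),
                 file.path(out, "profiles", paste0(id, ".log2.bedgraph")),
                 track_name = paste0(id, " log2 ratio"))
  write_bed(calls_bed(res$profile, grid),
            file.path(out, "profiles", paste0(id, ".calls.bed")))
  write_metrics_json(res$metrics, file.path(out, "metrics", paste0(id, ".json")),
                     flags = res$flags[setdiff(names(res$flags), "focal_amplifications")])
}
write_report(report, file.path(out, "cohort_report.tsv"))

cat(sprintf("scored %d samples: %d/%d tumors SCNA-positive, %d/%d controls positive\n",
            nrow(report$table),
            sum(report$table$scna_positive[report$table$group == "tumor"]),
            sum(report$table$group == "tumor"),
            sum(report$table$scna_positive[report$table$group == "control"]),
            sum(report$table$group == "control")))
print(report$table)
cat("wrote results/cohort_report.tsv, results/profiles/*, results/metrics/*\n")
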