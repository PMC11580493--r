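#!/usr/bin/env Rscript
# Stage 4: cohort summary. Re-reads the per-sample metrics JSONs written by
# stage 2, recomputes the group aggregates independently of the pipeline's
# own report, and prints a clinical-style "mean (range)" table.

suppressPackageStartupMessages(library(csfscna))
out <- "results"
truth <- utils::read.table(file.path(out, "truth.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)

rows <- lapply(truth$sample, function(id) {
  m <- read_metrics_json(file.path(out, "metrics", paste0(id, ".json")))
  fr <- m$tumor_fraction_score
  fr <- if (is.null(fr) || length(fr) != 1L) NA_real_ else as.numeric(fr)
  data.frame(sample_id = id,
             group = ifelse(truth$template[truth$sample == id] == "neutral",
                            "control", "tumor"),
             cni_score = as.numeric(m$cni_score),
             aberrant_bin_count = as.integer(m$aberrant_bin_count),
             scna_positive = isTRUE(m$scna_positive),
             tumor_fraction_score = fr,
             stringsAsFactors = FALSE)
})
tab <- do.call(rbind, rows)
agg <- cohort_aggregates(tab)
utils::write.table(agg, file.path(out, "cohort_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("cohort summary (mean (range)):\n")
for (i in seq_len(nrow(agg))) {
  a <- agg[i, ]
  cat(sprintf("  %-8s n=%d positive=%d | CNI %.1f (%.1f-%.1f) | bins %.0f (%.0f-%.0f) | fraction %.2f (%.2f-%.2f)\n",
              a$group, a$n, a$n_positive, a$cni_mean, a$cni_min, a$cni_max,
              a$bins_mean, a$bins_min, a$bins_max,
              a$fraction_mean, a$fraction_min, a$fraction_max))
}
cat("wrote results/cohort_summary.tsv\n")
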