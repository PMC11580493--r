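#' Pipeline configuration
#'
#' All analysis constants in one flat, serializable record. Defaults are the
#' published operating point of the assay: 5.5 Mbp non-overlapping bins on
#' HG19, MAPQ >= 60, aberration calls strictly beyond +/-0.1 log2, SCNA
#' positivity at >= 5 aberrant bins, sex chromosomes excluded from
#' normalization and scoring.
#'
#' @param bin_size bin width in bp.
#' @param step bin step in bp (= `bin_size` for non-overlapping tiling).
#' @param amp_threshold amplification call threshold (log2).
#' @param del_threshold deletion call threshold (log2).
#' @param positivity_min_bins aberrant bins needed for SCNA positivity.
#' @param min_mapq minimum mapping quality retained.
#' @param correction `"loess"` or `"median_bins"`.
#' @param genome_build reference build label.
#' @param seed master seed for any simulation steps.
#' @param include_sex_chromosomes include X/Y in normalization and scoring.
#' @param min_mappability bin-usability mappability cutoff.
#' @return a `pipeline_config` named list.
#' @export
pipeline_config <- function(bin_size = 5500000, step = bin_size,
                            amp_threshold = 0.1, del_threshold = -0.1,
                            positivity_min_bins = 5, min_mapq = 60,
                            correction = "loess", genome_build = "HG19",
                            seed = 1, include_sex_chromosomes = FALSE,
                            min_mappability = 0.5) {
  structure(list(bin_size = bin_size, step = step,
                 amp_threshold = amp_threshold, del_threshold = del_threshold,
                 positivity_min_bins = positivity_min_bins,
                 min_mapq = min_mapq, correction = correction,
                 genome_build = genome_build, seed = seed,
                 include_sex_chromosomes = include_sex_chromosomes,
                 min_mappability = min_mappability),
            class = c("pipeline_config", "list"))
}

#' Process one sample's raw counts through the scoring pipeline
#'
#' correct -> median-normalize/log2 -> call -> metrics (-> arm calls and
#' diagnostic flags when an arm table is supplied).
#'
#' @param raw a raw `bin_counts`.
#' @param grid annotated `bin_grid`.
#' @param config a `pipeline_config`.
#' @param arm_table optional arm table for flags (`NULL` skips them).
#' @param regions gene-region table for the CDKN2A/B flag.
#' @return list with `profile`, `metrics`, and (optionally) `arms`, `flags`.
#' @export
run_sample <- function(raw, grid, config = pipeline_config(),
                       arm_table = NULL, regions = NULL) {
  corrected <- correct_counts(raw, grid, method = config$correction)
  profile <- to_log2_profile(corrected, grid,
                             include_sex_chromosomes = config$include_sex_chromosomes)
  profile <- call_aberrant(profile, amp_thr = config$amp_threshold,
                           del_thr = config$del_threshold)
  metrics <- compute_metrics(profile, min_bins = config$positivity_min_bins)
  out <- list(profile = profile, metrics = metrics)
  if (!is.null(arm_table)) {
    out$arms <- arm_calls(profile, grid, arm_table)
    out$flags <- diagnostic_flags(out$arms, profile, grid, regions = regions)
  }
  out
}

#' Run the full analysis over a cohort of count sets
#'
#' Executes correct -> normalize -> call -> metrics (-> flags) per sample and
#' assembles the cohort report. Any stage failure is re-raised with the stage
#' and sample id.
#'
#' @param counts_list named list of raw `bin_counts` (names are sample ids),
#'   or the `samples` element of [simulate_cohort()].
#' @param grid annotated `bin_grid`.
#' @param config a `pipeline_config`.
#' @param groups optional named character vector sample -> group label.
#' @param arm_table optional arm table; enables diagnostic flags.
#' @param regions gene-region table for the CDKN2A/B flag.
#' @return a `cohort_report`: list with `samples` (per-sample results),
#'   `table` (per-sample data.frame) and `aggregates`.
#' @export
run_pipeline <- function(counts_list, grid, config = pipeline_config(),
                         groups = NULL, arm_table = NULL,
                         regions = NULL) {
  if (!length(counts_list)) stop("empty input list")
  samples <- lapply(names(counts_list), function(id) {
    x <- counts_list[[id]]
    raw <- if (inherits(x, "bin_counts")) x else x$counts
    tryCatch(run_sample(raw, grid, config, arm_table = arm_table,
                        regions = regions),
             error = function(e) stop("pipeline failed at sample '", id,
                                      "': ", conditionMessage(e), call. = FALSE))
  })
  names(samples) <- names(counts_list)
  tab <- do.call(rbind, lapply(names(samples), function(id) {
    m <- samples[[id]]$metrics
    data.frame(sample_id = id,
               group = if (!is.null(groups)) unname(groups[id]) else NA_character_,
               cni_score = m$cni_score,
               aberrant_bin_count = m$aberrant_bin_count,
               scna_positive = m$scna_positive,
               tumor_fraction_score = m$tumor_fraction_score,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(samples = samples, table = tab,
                 aggregates = cohort_aggregates(tab), config = config),
            class = "cohort_report")
}

#' Cohort aggregates: mean and range per group
#'
#' Recomputable from the per-sample rows; mirrors the
#' "mean (range)" presentation of clinical summary tables.
#'
#' @param table per-sample data.frame with `group`, `cni_score`,
#'   `aberrant_bin_count`, `tumor_fraction_score`, `scna_positive`.
#' @return data.frame, one row per group plus `all`.
#' @export
cohort_aggregates <- function(table) {
  groups <- unique(c("all", stats::na.omit(table$group)))
  do.call(rbind, lapply(groups, function(g) {
    rows <- if (g == "all") table else table[!is.na(table$group) & table$group == g, ]
    agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                         min = suppressWarnings(min(x, na.rm = TRUE)),
                         max = suppressWarnings(max(x, na.rm = TRUE)))
    cni <- agg(rows$cni_score); bins <- agg(rows$aberrant_bin_count)
    fr <- agg(rows$tumor_fraction_score)
    data.frame(group = g, n = nrow(rows),
               n_positive = sum(rows$scna_positive),
               cni_mean = cni["mean"], cni_min = cni["min"], cni_max = cni["max"],
               bins_mean = bins["mean"], bins_min = bins["min"], bins_max = bins["max"],
               fraction_mean = fr["mean"], fraction_min = fr["min"],
               fraction_max = fr["max"], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d sample(s), %d SCNA-positive\n",
              nrow(x$table), sum(x$table$scna_positive)))
  print(x$table)
  invisible(x)
}

#' Write the cohort report as TSV (machine table + rounded summary)
#'
#' The machine table keeps full precision; the appended human-readable
#' summary rows round the fraction score to two decimals and the CNI score
#' to integers above 10, in the style of a clinical results table.
#'
#' @param report a `cohort_report`.
#' @param path output TSV path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines("", con)
  writeLines("# group summaries: mean (range)", con)
  a <- report$aggregates
  fmt_cni <- function(v) ifelse(abs(v) > 10, sprintf("%.0f", v), sprintf("%.1f", v))
  for (i in seq_len(nrow(a))) {
    writeLines(sprintf("# %s\tn=%d\tpositive=%d\tCNI %s (%s-%s)\tbins %.0f (%.0f-%.0f)\tfraction %.2f (%.2f-%.2f)",
                       a$group[i], a$n[i], a$n_positive[i],
                       fmt_cni(a$cni_mean[i]), fmt_cni(a$cni_min[i]), fmt_cni(a$cni_max[i]),
                       a$bins_mean[i], a$bins_min[i], a$bins_max[i],
                       a$fraction_mean[i], a$fraction_min[i], a$fraction_max[i]), con)
  }
  invisible(path)
}

#' Build a called log2 profile directly from per-bin log2 ratios
#'
#' Convenience for analyses that start from an existing log2-ratio track
#' (e.g. one exported by another tool) rather than raw counts.
#'
#' @param log2r numeric vector (NA = masked bins).
#' @param sample_id sample label.
#' @param amp_thr,del_thr call thresholds.
#' @return a called `log2_profile`.
#' @export
profile_from_log2 <- function(log2r, sample_id = "sample",
                              amp_thr = 0.1, del_thr = -0.1) {
  p <- structure(list(sample_id = sample_id, log2r = as.numeric(log2r),
                      calls = integer(length(log2r)),
                      amp_threshold = amp_thr, del_threshold = del_thr,
                      scored = !is.na(log2r)),
                 class = "log2_profile")
  call_aberrant(p, amp_thr, del_thr)
}
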