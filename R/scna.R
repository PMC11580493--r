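#' Per-bin read-pair counts for one sample
#'
#' @param sample_id sample label.
#' @param counts numeric vector, one value per grid bin; raw counts must be
#'   non-negative integers, corrected counts non-negative reals (`NA` for
#'   masked bins).
#' @param stage `"raw"` or `"corrected"`.
#' @return a `bin_counts` object.
#' @export
bin_counts <- function(sample_id, counts, stage = c("raw", "corrected")) {
  stage <- match.arg(stage)
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (stage == "raw" && any(counts %% 1 != 0, na.rm = TRUE))
    stop("raw counts must be integers")
  structure(list(sample_id = sample_id, counts = counts, stage = stage),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts '%s' (%s): %d bins, total %.0f\n",
              x$sample_id, x$stage, length(x$counts), sum(x$counts, na.rm = TRUE)))
  invisible(x)
}

# SAM flag bits
FLAG_PAIRED <- 0x1; FLAG_PROPER <- 0x2; FLAG_UNMAPPED <- 0x4
FLAG_FIRST <- 0x40; FLAG_SECONDARY <- 0x100; FLAG_DUP <- 0x400
FLAG_SUPPLEMENTARY <- 0x800

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), as.integer(bit)) != 0L

#' Read alignment records from SAM or BAM
#'
#' Loads the fields the counting path needs (`qname`, `flag`, `chrom`, `pos`,
#' `mapq`, `mpos`). SAM input is converted through `Rsamtools::asBam()`.
#' Positions are 1-based as in SAM.
#'
#' @param path SAM or BAM file.
#' @return data.frame of alignment records.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "mpos")))[[1]]
  data.frame(qname = res$qname, flag = as.integer(res$flag),
             chrom = as.character(res$rname), pos = res$pos,
             mapq = res$mapq, mpos = res$mpos, stringsAsFactors = FALSE)
}

#' Filter alignment records for counting
#'
#' Retains primary, properly paired, non-duplicate records with mapping
#' quality at or above `min_mapq` (records with MAPQ strictly below the
#' threshold are removed). Also returns the QC tallies the filter implies.
#'
#' @param records data.frame from [read_alignments()].
#' @param min_mapq minimum mapping quality retained (default 60).
#' @return list with `records` (the surviving rows) and `tallies`
#'   (`total_records`, `mapped_records`, `filtered_records`,
#'   `filtered_pairs`).
#' @export
filter_alignments <- function(records, min_mapq = 60) {
  total <- nrow(records)
  if (total == 0L) {
    return(list(records = records,
                tallies = list(total_records = 0L, mapped_records = 0L,
                               filtered_records = 0L, filtered_pairs = 0L)))
  }
  mapped <- !has_flag(records$flag, FLAG_UNMAPPED)
  keep <- mapped &
    has_flag(records$flag, FLAG_PAIRED) &
    has_flag(records$flag, FLAG_PROPER) &
    !has_flag(records$flag, FLAG_DUP) &
    !has_flag(records$flag, FLAG_SECONDARY) &
    !has_flag(records$flag, FLAG_SUPPLEMENTARY) &
    !is.na(records$mapq) & records$mapq >= min_mapq
  out <- records[keep, , drop = FALSE]
  list(records = out,
       tallies = list(total_records = total,
                      mapped_records = sum(mapped),
                      filtered_records = nrow(out),
                      filtered_pairs = length(unique(out$qname))))
}

#' Count read pairs per grid bin
#'
#' Each pair is counted once, in the bin containing the start coordinate of
#' its leftmost mate. Pairs on chromosomes absent from the grid, or starting
#' beyond the last bin of their chromosome, are dropped (with a warning for
#' unknown chromosomes) and tallied.
#'
#' @param filtered data.frame of filtered records (see [filter_alignments()]),
#'   or the list that function returns.
#' @param grid a `bin_grid` (requires `step == bin_size`).
#' @param sample_id sample label for the result.
#' @return a raw `bin_counts`; attribute `dropped` holds the number of
#'   uncounted pairs.
#' @export
count_pairs_in_bins <- function(filtered, grid, sample_id = "sample") {
  if (is.list(filtered) && !is.data.frame(filtered)) filtered <- filtered$records
  if (attr(grid, "step") != attr(grid, "bin_size"))
    stop("pair counting requires a non-overlapping grid (step == bin_size)")

  counts <- numeric(nrow(grid))
  dropped <- 0L
  if (nrow(filtered)) {
    # one record per pair: the leftmost mate (ties broken by first-in-pair)
    leftmost <- filtered$pos < filtered$mpos |
      (filtered$pos == filtered$mpos & has_flag(filtered$flag, FLAG_FIRST))
    pairs <- filtered[leftmost, , drop = FALSE]
    unknown <- !(pairs$chrom %in% unique(grid$chrom))
    if (any(unknown)) {
      warning("dropping ", sum(unknown),
              " pair(s) on chromosome(s) absent from grid: ",
              paste(unique(pairs$chrom[unknown]), collapse = ", "))
      dropped <- dropped + sum(unknown)
      pairs <- pairs[!unknown, , drop = FALSE]
    }
    if (nrow(pairs)) {
      bin_size <- attr(grid, "bin_size")
      # grid is sorted by chrom; index bins by (chrom, floor(start0/bin_size))
      key_grid <- paste(grid$chrom, grid$start %/% bin_size)
      start0 <- pairs$pos - 1
      key_pair <- paste(pairs$chrom, start0 %/% bin_size)
      idx <- match(key_pair, key_grid)
      in_bin <- !is.na(idx) & start0 >= 0 &
        start0 >= grid$start[idx] & start0 < grid$end[idx]
      dropped <- dropped + sum(!in_bin)
      tab <- tabulate(idx[in_bin], nbins = nrow(grid))
      counts <- as.numeric(tab)
    }
  }
  out <- bin_counts(sample_id, counts, stage = "raw")
  attr(out, "dropped") <- dropped
  out
}

#' Correct bin counts for GC content and mappability
#'
#' Divides length-normalized raw counts by a fitted GC/mappability bias term,
#' normalized to mean 1 over usable bins, so the corrected counts stay on the
#' raw-count scale. Two fits are available: `median_bins` (the transparent
#' oracle: median count per GC decile, scaled linearly by mappability) and
#' `loess` (smooth fit of mappability-adjusted counts against GC). With fewer
#' than 30 usable bins `loess` falls back to `median_bins` with a warning.
#' Unusable bins are masked (`NA`).
#'
#' @param raw a raw `bin_counts`.
#' @param grid annotated `bin_grid` (GC and mappability on usable bins).
#' @param method `"loess"` (default) or `"median_bins"`.
#' @return corrected `bin_counts`.
#' @export
correct_counts <- function(raw, grid, method = c("loess", "median_bins")) {
  method <- match.arg(method)
  stopifnot(inherits(raw, "bin_counts"))
  if (length(raw$counts) != nrow(grid))
    stop("counts length does not match grid")
  use <- grid$usable
  if (!any(use)) stop("no usable bins")
  if (any(is.na(grid$gc[use])) || any(is.na(grid$mappability[use])))
    stop("gc and mappability must be annotated on all usable bins")

  lenfrac <- (grid$end - grid$start) / attr(grid, "bin_size")
  x <- raw$counts / lenfrac                # length-normalized counts
  gc <- grid$gc; mp <- grid$mappability

  if (method == "loess" && sum(use) < 30) {
    warning("fewer than 30 usable bins; falling back to median_bins correction")
    method <- "median_bins"
  }

  fit <- rep(NA_real_, nrow(grid))
  if (method == "median_bins") {
    mp_ref <- mean(mp[use])
    adj <- x / ifelse(mp > 0, mp / mp_ref, NA_real_)
    breaks <- unique(stats::quantile(gc[use], probs = seq(0, 1, by = 0.1),
                                     na.rm = TRUE, names = FALSE))
    if (length(breaks) < 2) {
      # constant GC: a single global median, nothing GC-shaped to remove
      fit[use] <- stats::median(adj[use], na.rm = TRUE) * (mp[use] / mp_ref)
    } else {
      dec <- cut(gc, breaks = breaks, include.lowest = TRUE)
      med <- tapply(adj[use], dec[use], stats::median, na.rm = TRUE)
      ctr <- tapply(gc[use], dec[use], stats::median, na.rm = TRUE)
      ok <- !is.na(med) & !is.na(ctr)
      gc_fit <- if (sum(ok) >= 2) {
        stats::approx(ctr[ok], med[ok], xout = gc[use], rule = 2)$y
      } else rep(stats::median(adj[use], na.rm = TRUE), sum(use))
      fit[use] <- gc_fit * (mp[use] / mp_ref)
    }
  } else {
    mp_ref <- mean(mp[use])
    adj <- x[use] / ifelse(mp[use] > 0, mp[use] / mp_ref, NA_real_)
    lo <- stats::loess(adj ~ gc[use], span = 0.5, degree = 2,
                       family = "symmetric",
                       control = stats::loess.control(surface = "direct"))
    fit[use] <- stats::predict(lo, newdata = gc[use]) * (mp[use] / mp_ref)
  }
  fit[fit <= 0] <- NA_real_
  fit_mean <- mean(fit[use], na.rm = TRUE)
  corrected <- ifelse(use & !is.na(fit), x / (fit / fit_mean), NA_real_)
  bin_counts(raw$sample_id, corrected, stage = "corrected")
}

#' Median-normalize corrected counts into a log2-ratio profile
#'
#' Each usable bin's corrected count is divided by the median corrected count
#' over usable autosomal bins (sex chromosomes are excluded from the median by
#' default, since germline sex would masquerade as a somatic change) and
#' log2-transformed. Ratios are floored at `floor` (default 2^-8) so
#' zero-count, homozygous-deletion-like bins keep a finite log2 ratio.
#' Unusable bins are masked.
#'
#' @param corrected a corrected `bin_counts` (raw accepted, with a note that
#'   no correction was applied).
#' @param grid the `bin_grid`.
#' @param include_sex_chromosomes include X/Y in the median and downstream
#'   scoring (default `FALSE`).
#' @param floor minimum ratio before log2 (default `2^-8`).
#' @return a `log2_profile`: list with `sample_id`, `log2r` (NA-masked),
#'   `calls` (all 0 until [call_aberrant()]), thresholds, and a `scored`
#'   logical marking bins that enter the metrics.
#' @export
to_log2_profile <- function(corrected, grid, include_sex_chromosomes = FALSE,
                            floor = 2^-8) {
  stopifnot(inherits(corrected, "bin_counts"))
  if (length(corrected$counts) != nrow(grid))
    stop("counts length does not match grid")
  scored <- scoring_bins(grid, include_sex_chromosomes) & !is.na(corrected$counts)
  vals <- corrected$counts[scored]
  if (!length(vals) || all(vals == 0)) stop("insufficient coverage")
  med <- stats::median(vals)
  if (med == 0) stop("insufficient coverage: median corrected count is zero")
  keep <- grid$usable & !is.na(corrected$counts)
  log2r <- rep(NA_real_, nrow(grid))
  log2r[keep] <- log2(pmax(corrected$counts[keep] / med, floor))
  structure(list(sample_id = corrected$sample_id, log2r = log2r,
                 calls = integer(nrow(grid)),
                 amp_threshold = 0.1, del_threshold = -0.1,
                 scored = scored),
            class = "log2_profile")
}

#' @export
print.log2_profile <- function(x, ...) {
  cat(sprintf("log2_profile '%s': %d bins (%d scored), %d called aberrant\n",
              x$sample_id, length(x$log2r), sum(x$scored), sum(x$calls != 0)))
  invisible(x)
}

#' Call aberrant bins on a log2-ratio profile
#'
#' A bin is called amplified (+1) when its log2 ratio is strictly above
#' `amp_thr` and deleted (-1) when strictly below `del_thr`; a ratio exactly
#' at a threshold stays neutral. Masked bins and bins outside the scored set
#' are never called.
#'
#' @param profile a `log2_profile`.
#' @param amp_thr amplification threshold (default +0.1).
#' @param del_thr deletion threshold (default -0.1).
#' @return the profile with `calls` filled.
#' @export
call_aberrant <- function(profile, amp_thr = 0.1, del_thr = -0.1) {
  stopifnot(inherits(profile, "log2_profile"))
  if (del_thr >= amp_thr) stop("del_thr must be below amp_thr")
  calls <- integer(length(profile$log2r))
  ok <- profile$scored & !is.na(profile$log2r)
  calls[ok & profile$log2r > amp_thr] <- 1L
  calls[ok & profile$log2r < del_thr] <- -1L
  profile$calls <- calls
  profile$amp_threshold <- amp_thr
  profile$del_threshold <- del_thr
  profile
}

#' Compute the three SCNA diagnostic metrics
#'
#' From the aberrant-bin calls of a profile: the CNI (chromosomal number
#' instability) score is the sum of absolute log2 ratios over called bins;
#' the aberrant-bin count is the number of called bins, with the sample
#' deemed SCNA-positive at `min_bins` or more; and the tumor-cfDNA fraction
#' score is the CNI score divided by the aberrant-bin count (the mean
#' aberrant-bin |log2 ratio|, a proxy for the tumor-derived cfDNA level),
#' undefined (`NA`) when no bin is aberrant.
#'
#' @param profile a `log2_profile` with calls filled.
#' @param min_bins positivity threshold on the aberrant-bin count, inclusive
#'   (default 5).
#' @return an `scna_metrics` list: `sample_id`, `cni_score`,
#'   `aberrant_bin_count`, `scna_positive`, `tumor_fraction_score`,
#'   `positivity_min_bins`.
#' @export
compute_metrics <- function(profile, min_bins = 5) {
  stopifnot(inherits(profile, "log2_profile"))
  called <- profile$calls != 0L
  cni <- sum(abs(profile$log2r[called]))
  n_ab <- sum(called)
  structure(list(sample_id = profile$sample_id,
                 cni_score = cni,
                 aberrant_bin_count = as.integer(n_ab),
                 scna_positive = n_ab >= min_bins,
                 tumor_fraction_score = if (n_ab > 0) cni / n_ab else NA_real_,
                 positivity_min_bins = as.integer(min_bins)),
            class = "scna_metrics")
}

#' @export
print.scna_metrics <- function(x, ...) {
  cat(sprintf("scna_metrics '%s': CNI %.2f, aberrant bins %d, %s, fraction score %s\n",
              x$sample_id, x$cni_score, x$aberrant_bin_count,
              if (x$scna_positive) "SCNA-positive" else "SCNA-negative",
              if (is.na(x$tumor_fraction_score)) "NA"
              else sprintf("%.2f", x$tumor_fraction_score)))
  invisible(x)
}

#' Sequencing QC metrics
#'
#' @param total_reads total sequenced reads.
#' @param mapped_reads reads mapped to the reference.
#' @param filtered_pairs read pairs surviving duplicate/MAPQ filtering.
#' @param read_length read length in bp (default 75).
#' @param genome_size reference size in bp (default 3.1e9).
#' @param min_mapq the MAPQ cutoff the filtering used (recorded; default 60).
#' @return a `qc_metrics` list with `total_reads`, `mapped_reads`,
#'   `mapped_fraction`, `filtered_read_pairs`, `mean_coverage_depth`
#'   (= filtered pairs x 2 x read length / genome size) and `min_mapq`.
#' @export
qc_metrics <- function(total_reads, mapped_reads, filtered_pairs,
                       read_length = 75, genome_size = 3.1e9, min_mapq = 60) {
  stopifnot(total_reads >= 0, mapped_reads >= 0, filtered_pairs >= 0)
  if (mapped_reads > total_reads) stop("mapped_reads exceeds total_reads")
  structure(list(
    total_reads = total_reads,
    mapped_reads = mapped_reads,
    mapped_fraction = if (total_reads > 0) mapped_reads / total_reads else NA_real_,
    filtered_read_pairs = filtered_pairs,
    mean_coverage_depth = filtered_pairs * 2 * read_length / genome_size,
    min_mapq = min_mapq), class = "qc_metrics")
}

#' Export a profile's log2 ratios as a bedGraph data.frame
#'
#' @param profile a `log2_profile`.
#' @param grid the matching `bin_grid`.
#' @param drop_masked drop bins with masked log2 ratios (default `TRUE`).
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
profile_track <- function(profile, grid, drop_masked = TRUE) {
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   value = profile$log2r)
  if (drop_masked) df <- df[!is.na(df$value), ]
  rownames(df) <- NULL
  df
}

#' Export aberrant-bin calls as a BED data.frame
#'
#' @param profile a called `log2_profile`.
#' @param grid the matching `bin_grid`.
#' @return data.frame `chrom`, `start`, `end`, `name` with name AMP/DEL.
#' @export
calls_bed <- function(profile, grid) {
  idx <- which(profile$calls != 0L)
  data.frame(chrom = grid$chrom[idx], start = grid$start[idx],
             end = grid$end[idx],
             name = ifelse(profile$calls[idx] > 0, "AMP", "DEL"),
             stringsAsFactors = FALSE)
}
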