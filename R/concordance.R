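# Paired-profile concordance (CSF vs tissue, serial CSF) and rule-based
# diagnostic flags for WHO-relevant copy-number patterns. The unit of
# comparison is the bin, direction-aware: bins aberrant in both profiles but
# in opposite directions are reported separately, not folded into "shared".

same_grid <- function(a, b) {
  length(a$log2r) == length(b$log2r) && length(a$scored) == length(b$scored)
}

#' Bin-level concordance of two SCNA profiles
#'
#' Classifies every bin in the union of aberrant bins of two called profiles
#' on the same grid: `shared` (same nonzero call in both), `private_a` /
#' `private_b` (aberrant in exactly one), and `discordant_direction`
#' (aberrant in both, opposite sign). Fractions are of the union.
#'
#' @param a,b called `log2_profile` objects on the identical bin grid.
#' @return a `concordance_result` list with counts, fractions and `union`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "log2_profile"), inherits(b, "log2_profile"))
  if (!same_grid(a, b))
    stop("profiles are not on the same bin grid (", length(a$log2r), " vs ",
         length(b$log2r), " bins); no silent lift-over")
  ca <- a$calls; cb <- b$calls
  union_ab <- ca != 0L | cb != 0L
  shared <- sum(ca != 0L & ca == cb)
  discordant <- sum(ca != 0L & cb != 0L & ca != cb)
  private_a <- sum(ca != 0L & cb == 0L)
  private_b <- sum(cb != 0L & ca == 0L)
  n_union <- sum(union_ab)
  frac <- function(x) if (n_union > 0) x / n_union else NA_real_
  structure(list(sample_a = a$sample_id, sample_b = b$sample_id,
                 shared = shared, private_a = private_a, private_b = private_b,
                 discordant_direction = discordant, union = n_union,
                 shared_fraction = frac(shared),
                 private_a_fraction = frac(private_a),
                 private_b_fraction = frac(private_b),
                 discordant_fraction = frac(discordant)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance %s vs %s: union %d | shared %d (%.2f) | private A %d | private B %d | discordant %d\n",
    x$sample_a, x$sample_b, x$union, x$shared,
    ifelse(is.na(x$shared_fraction), NaN, x$shared_fraction),
    x$private_a, x$private_b, x$discordant_direction))
  invisible(x)
}

#' Concordance along a series of profiles
#'
#' Compares consecutive profiles of an ordered series (e.g. serial CSF
#' samples over time) and summarizes stability as the minimum shared
#' fraction.
#'
#' @param profiles ordered list of >= 2 called `log2_profile`s on one grid.
#' @return list with `pairs` (list of `concordance_result`) and
#'   `min_shared_fraction`.
#' @export
longitudinal_stability <- function(profiles) {
  if (length(profiles) < 2L)
    stop("need at least two profiles for a longitudinal comparison")
  pairs <- lapply(seq_len(length(profiles) - 1L), function(i)
    compare_profiles(profiles[[i]], profiles[[i + 1L]]))
  shared <- vapply(pairs, function(p) p$shared_fraction, numeric(1))
  list(pairs = pairs, min_shared_fraction = suppressWarnings(min(shared, na.rm = TRUE)))
}

bin_arm_assignment <- function(grid, arm_table) {
  missing_chroms <- setdiff(unique(grid$chrom), unique(arm_table$chrom))
  if (length(missing_chroms))
    stop("arm table does not cover chromosome(s): ",
         paste(missing_chroms, collapse = ", "))
  mid <- (grid$start + grid$end) / 2
  arm <- rep(NA_character_, nrow(grid))
  for (i in seq_len(nrow(arm_table))) {
    hit <- grid$chrom == arm_table$chrom[i] &
      mid >= arm_table$start[i] & mid < arm_table$end[i]
    arm[hit] <- arm_table$arm[i]
  }
  arm
}

#' Chromosome-arm-level gain/loss calls
#'
#' Bins are assigned to the arm containing their midpoint (centromere-gap
#' bins stay unassigned). An arm is called `gain` when at least
#' `min_arm_fraction` of its usable scored bins carry +1 calls, `loss`
#' analogously; otherwise `neutral`. Arms without usable bins are neutral
#' with covered fraction 0.
#'
#' @param profile a called `log2_profile`.
#' @param grid the matching `bin_grid`.
#' @param arm_table data.frame `chrom`, `start`, `end`, `arm` (e.g.
#'   [hg19_arm_table()]) or a TSV path in that layout.
#' @param min_arm_fraction call threshold on the fraction of aberrant bins
#'   (default 0.6).
#' @return data.frame of `arm_call`s: `arm`, `state`, `mean_log2`,
#'   `covered_fraction`, `n_bins`.
#' @export
arm_calls <- function(profile, grid, arm_table = hg19_arm_table(),
                      min_arm_fraction = 0.6) {
  stopifnot(inherits(profile, "log2_profile"))
  if (is.character(arm_table))
    arm_table <- read_tsv_checked(arm_table, c("chrom", "start", "end", "arm"),
                                  NA, header = TRUE)
  arm_table$chrom <- as.character(arm_table$chrom)
  arm <- bin_arm_assignment(grid, arm_table)

  out <- lapply(arm_table$arm, function(a) {
    idx <- which(arm == a & profile$scored & !is.na(profile$log2r))
    if (!length(idx))
      return(data.frame(arm = a, state = "neutral", mean_log2 = NA_real_,
                        covered_fraction = 0, n_bins = 0L,
                        stringsAsFactors = FALSE))
    calls <- profile$calls[idx]
    gain_f <- mean(calls == 1L)
    loss_f <- mean(calls == -1L)
    state <- "neutral"; covered <- max(gain_f, loss_f)
    if (gain_f >= min_arm_fraction && gain_f >= loss_f) state <- "gain"
    else if (loss_f >= min_arm_fraction) state <- "loss"
    data.frame(arm = a, state = state,
               mean_log2 = mean(profile$log2r[idx]),
               covered_fraction = covered, n_bins = length(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

arm_state <- function(arms, name) {
  s <- arms$state[arms$arm == name]
  if (!length(s)) "neutral" else s[1]
}

#' CDKN2A/B locus (HG19)
#'
#' The 9p21.3 region spanning CDKN2A and CDKN2B, 0-based half-open, as
#' shipped in `inst/extdata/cdkn2ab_hg19.bed`.
#'
#' @return data.frame `chrom`, `start`, `end`, `name`.
#' @export
cdkn2ab_region <- function() {
  read_bed(system.file("extdata", "cdkn2ab_hg19.bed", package = "csfscna"))
}

#' Rule-based diagnostic SCNA flags
#'
#' Evaluates WHO-relevant copy-number patterns from arm calls and the bin
#' profile: `plus7_minus10` (7p and 7q gain with 10p and 10q loss — the
#' IDH-wildtype glioblastoma pattern), `codel_1p19q` (1p and 19q loss —
#' oligodendroglioma), `del_6q` (6q loss, recurrent in CNS lymphoma),
#' `cdkn2ab_homdel` (any bin overlapping the supplied gene region with log2
#' ratio below `deep_del_log2`, a deep-deletion level consistent with a
#' homozygous event), and `focal_amplifications` (maximal runs of at most
#' `max_focal_bins` consecutive +1 bins whose peak log2 ratio exceeds
#' `focal_amp_log2`). Flags are deterministic functions of the calls; they
#' are inputs to human interpretation, not a diagnosis.
#'
#' @param arms data.frame from [arm_calls()].
#' @param profile the same called `log2_profile`.
#' @param grid the matching `bin_grid`.
#' @param regions gene-region data.frame/BED path with the CDKN2A/B locus,
#'   or `NULL` to skip that flag (flag becomes `NA` with a warning).
#' @param deep_del_log2 deep-deletion threshold (default -1.0; for pure cn 0
#'   this corresponds to tumor fraction > 0.5, less for focal events).
#' @param focal_amp_log2 focal-amplification peak threshold (default 0.58,
#'   i.e. ratio 1.5).
#' @param max_focal_bins maximum run length still considered focal (default 3).
#' @return a `diagnostic_flags` list.
#' @export
diagnostic_flags <- function(arms, profile, grid, regions = cdkn2ab_region(),
                             deep_del_log2 = -1.0, focal_amp_log2 = 0.58,
                             max_focal_bins = 3L) {
  stopifnot(inherits(profile, "log2_profile"))

  plus7_minus10 <- arm_state(arms, "7p") == "gain" &&
    arm_state(arms, "7q") == "gain" &&
    arm_state(arms, "10p") == "loss" && arm_state(arms, "10q") == "loss"
  codel_1p19q <- arm_state(arms, "1p") == "loss" && arm_state(arms, "19q") == "loss"
  del_6q <- arm_state(arms, "6q") == "loss"

  cdkn2ab <- NA
  if (is.null(regions)) {
    warning("no gene-region file supplied; cdkn2ab_homdel flag is NA")
  } else {
    if (is.character(regions)) regions <- read_bed(regions)
    hit <- rep(FALSE, nrow(grid))
    for (i in seq_len(nrow(regions))) {
      hit <- hit | (grid$chrom == sub("^chr", "", regions$chrom[i]) &
                      grid$start < regions$end[i] & grid$end > regions$start[i])
    }
    cdkn2ab <- any(hit & !is.na(profile$log2r) & profile$log2r < deep_del_log2)
  }

  # maximal runs of consecutive +1 calls within a chromosome
  focal <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), max_log2 = numeric(),
                      stringsAsFactors = FALSE)
  amp <- profile$calls == 1L
  r <- rle(paste0(grid$chrom, "_", amp))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (!grepl("_TRUE$", r$values[j])) next
    idx <- starts[j]:ends[j]
    if (length(idx) > max_focal_bins) next
    peak <- max(profile$log2r[idx], na.rm = TRUE)
    if (peak > focal_amp_log2)
      focal <- rbind(focal, data.frame(
        chrom = grid$chrom[idx[1]], start = grid$start[idx[1]],
        end = grid$end[idx[length(idx)]], n_bins = length(idx),
        max_log2 = peak, stringsAsFactors = FALSE))
  }

  structure(list(sample_id = profile$sample_id,
                 plus7_minus10 = plus7_minus10,
                 codel_1p19q = codel_1p19q,
                 cdkn2ab_homdel = cdkn2ab,
                 del_6q = del_6q,
                 focal_amplifications = focal),
            class = "diagnostic_flags")
}

#' @export
print.diagnostic_flags <- function(x, ...) {
  cat(sprintf("diagnostic_flags '%s': +7/-10 %s | 1p/19q codel %s | CDKN2A/B homdel %s | 6q del %s | %d focal amp(s)\n",
              x$sample_id, x$plus7_minus10, x$codel_1p19q, x$cdkn2ab_homdel,
              x$del_6q, nrow(x$focal_amplifications)))
  invisible(x)
}
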