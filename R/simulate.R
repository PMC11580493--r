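# Synthetic shallow-WGS cfDNA data: segment-level copy-number truth profiles,
# a tumor/normal mixture model for expected per-bin ratios, and an
# overdispersed count sampler. Stands in for patient data so the whole
# pipeline is testable end to end.

#' Segment-level copy-number profile (simulation ground truth)
#'
#' @param name profile label.
#' @param segments data.frame `chrom`, `start`, `end`, `cn` (0-based
#'   half-open; integer copy number >= 0). Positions not covered by any
#'   segment carry `default_cn`.
#' @param default_cn baseline copy number (default 2, diploid).
#' @return a `cn_profile` object.
#' @export
cn_profile <- function(name, segments = NULL, default_cn = 2L) {
  if (is.null(segments))
    segments <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), cn = integer())
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(segments)))
  if (nrow(segments)) {
    if (any(segments$start >= segments$end)) stop("segment start must be < end")
    if (any(segments$cn < 0)) stop("copy number must be >= 0")
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping segments on chromosome ", ch)
    }
  }
  structure(list(name = name, segments = segments,
                 default_cn = as.numeric(default_cn)),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile '%s': %d segment(s), baseline cn %g\n",
              x$name, nrow(x$segments), x$default_cn))
  invisible(x)
}

#' Built-in copy-number truth templates
#'
#' Returns a `cn_profile` on HG19 coordinates for the canonical diagnostic
#' patterns: `neutral` (no aberration), `gbm_7p10q` (whole chromosome 7 gain
#' to cn 3 and chromosome 10 loss to cn 1, the glioblastoma +7/-10 pattern),
#' `oligo_1p19q` (single-copy loss of arms 1p and 19q, the oligodendroglioma
#' codeletion), `cdkn2ab_homdel` (focal homozygous deletion, cn 0, of two
#' bins on 9p21 spanning the CDKN2A/B locus), `lymphoma_6q` (single-copy
#' loss of 6q) and `focal_amp` (one-bin amplification to cn 10 on 12q).
#' Focal segments are aligned to default 5.5 Mbp bin boundaries.
#'
#' @param name template name.
#' @return a `cn_profile`.
#' @export
template_profile <- function(name) {
  templates <- c("neutral", "gbm_7p10q", "oligo_1p19q", "cdkn2ab_homdel",
                 "lymphoma_6q", "focal_amp")
  if (!is.character(name) || length(name) != 1L || !name %in% templates)
    stop("unknown template '", name, "'; available: ",
         paste(templates, collapse = ", "))
  sizes <- hg19_chrom_sizes()
  cen <- hg19_centromeres()
  seg <- function(chrom, start, end, cn)
    data.frame(chrom = chrom, start = start, end = end, cn = cn,
               stringsAsFactors = FALSE)
  segments <- switch(
    name,
    neutral = NULL,
    gbm_7p10q = rbind(seg("7", 0, sizes[["7"]], 3),
                      seg("10", 0, sizes[["10"]], 1)),
    oligo_1p19q = rbind(
      seg("1", 0, cen$cen_start[cen$chrom == "1"], 1),
      seg("19", cen$cen_end[cen$chrom == "19"], sizes[["19"]], 1)),
    cdkn2ab_homdel = seg("9", 16500000, 27500000, 0),
    lymphoma_6q = seg("6", cen$cen_end[cen$chrom == "6"], sizes[["6"]], 1),
    focal_amp = seg("12", 55000000, 60500000, 10))
  cn_profile(name, segments)
}

#' Length-weighted mean copy number per bin
#'
#' @param profile a `cn_profile`.
#' @param grid a `bin_grid`.
#' @return numeric vector of mean copy number over each bin.
#' @export
bin_mean_cn <- function(profile, grid) {
  cn <- rep(profile$default_cn, nrow(grid))
  seg <- profile$segments
  if (!nrow(seg)) return(cn)
  width <- grid$end - grid$start
  delta <- numeric(nrow(grid))
  for (i in seq_len(nrow(seg))) {
    on_chrom <- grid$chrom == seg$chrom[i]
    ov <- pmax(0, pmin(grid$end, seg$end[i]) - pmax(grid$start, seg$start[i]))
    ov[!on_chrom] <- 0
    delta <- delta + ov * (seg$cn[i] - profile$default_cn)
  }
  cn + delta / width
}

#' Expected bin-level coverage ratio of a tumor/normal cfDNA mixture
#'
#' A cfDNA sample with tumor fraction `f` mixes tumor DNA at copy number `cn`
#' with diploid normal DNA, giving a relative coverage of
#' `((1 - f) * 2 + f * cn) / 2` per bin, where `cn` is the bin's
#' length-weighted mean copy number. At `f = 0` or on neutral segments the
#' ratio is 1.
#'
#' @param profile a `cn_profile`.
#' @param f tumor fraction in \[0,1\].
#' @param grid a `bin_grid`.
#' @return numeric vector of expected ratios (>= 0), one per bin.
#' @export
expected_bin_ratio <- function(profile, f, grid) {
  if (f < 0 || f > 1) stop("tumor fraction must be in [0,1]")
  ((1 - f) * 2 + f * bin_mean_cn(profile, grid)) / 2
}

#' Multiplicative GC bias curve
#'
#' Smooth unimodal bias `exp(slope * (gc - center) + curvature * (gc - center)^2)`.
#' The default (`center` 0.45, `slope` 0, `curvature` -8) is gentle: about a
#' 20% depth deficit at GC 0.3 or 0.6 relative to the mode, so GC correction
#' is exercised without dominating the signal.
#'
#' @param gc numeric vector of GC fractions.
#' @param coef named list/vector with `center`, `slope`, `curvature`.
#' @return multiplicative bias factors.
#' @export
gc_bias_curve <- function(gc, coef = default_gc_bias()) {
  d <- gc - coef[["center"]]
  exp(coef[["slope"]] * d + coef[["curvature"]] * d^2)
}

#' @rdname gc_bias_curve
#' @export
default_gc_bias <- function() c(center = 0.45, slope = 0, curvature = -8)

#' Simulation specification for one cfDNA sample
#'
#' @param profile a `cn_profile` (the truth).
#' @param tumor_fraction tumor-derived fraction of the cfDNA, in \[0,1\].
#' @param total_pairs expected total filtered read pairs over usable bins
#'   (default 2e6; per-bin depth sets the log2-ratio noise, and this default
#'   keeps the noise well inside the fixed +/-0.1 call threshold — see the
#'   methods vignette).
#' @param gc_bias coefficients for [gc_bias_curve()].
#' @param dispersion negative-binomial overdispersion (variance =
#'   mean + dispersion * mean^2); 0 gives Poisson counts. Default 1e-4.
#' @param seed integer RNG seed for this sample.
#' @param sample_id sample label (default: profile name).
#' @return a `sim_spec` object.
#' @export
sim_spec <- function(profile, tumor_fraction, total_pairs = 2e6,
                     gc_bias = default_gc_bias(), dispersion = 1e-4,
                     seed = 1L, sample_id = profile$name) {
  stopifnot(inherits(profile, "cn_profile"))
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0,1]")
  if (total_pairs <= 0) stop("total_pairs must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(profile = profile, tumor_fraction = tumor_fraction,
                 total_pairs = total_pairs, gc_bias = gc_bias,
                 dispersion = dispersion, seed = as.integer(seed),
                 sample_id = sample_id),
            class = "sim_spec")
}

# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-sample seed from a cohort master seed
#'
#' Deterministic, collision-resistant within a cohort, and kept below 2^31.
#'
#' @param master_seed integer master seed.
#' @param index sample index (1-based).
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 16807) %% 2147483647)
}

#' Annotate a bin grid with synthetic GC and mappability
#'
#' Draws per-bin GC fractions (normal around 0.41, sd 0.05, clipped to
#' \[0.28, 0.65\] — the range of real 5.5 Mbp human windows) and high
#' mappability (Beta(30, 2), mostly 0.85-0.99), mimicking an annotated real
#' grid without shipping one.
#'
#' @param grid a `bin_grid`.
#' @param seed integer seed.
#' @return the annotated grid.
#' @export
annotate_synthetic <- function(grid, seed = 1L) {
  n <- nrow(grid)
  with_seed(seed, {
    grid$gc <- pmin(0.65, pmax(0.28, stats::rnorm(n, mean = 0.41, sd = 0.05)))
    grid$mappability <- stats::rbeta(n, 30, 2)
  })
  grid
}

#' Simulate per-bin read-pair counts for one cfDNA sample
#'
#' Per-bin expected counts are proportional to the mixture ratio from
#' [expected_bin_ratio()] times the GC bias, the bin's mappability and its
#' length fraction, scaled so the expectation over usable bins sums to
#' `total_pairs`. Counts are drawn negative-binomially (Poisson when
#' `dispersion = 0`); the draw is fully determined by `spec$seed`.
#'
#' @param spec a `sim_spec`.
#' @param grid an annotated `bin_grid`.
#' @return a raw `bin_counts`; attribute `lambda` holds the per-bin
#'   expectations.
#' @export
simulate_counts <- function(spec, grid) {
  stopifnot(inherits(spec, "sim_spec"))
  use <- grid$usable
  if (!any(use)) stop("all bins unusable")
  if (any(is.na(grid$gc[use])) || any(is.na(grid$mappability[use])))
    stop("grid must be annotated (see annotate_synthetic or annotate_gc/annotate_track)")

  ratio <- expected_bin_ratio(spec$profile, spec$tumor_fraction, grid)
  lenfrac <- (grid$end - grid$start) / attr(grid, "bin_size")
  lambda <- ratio * gc_bias_curve(grid$gc, spec$gc_bias) *
    grid$mappability * lenfrac
  lambda[is.na(lambda)] <- 0
  scale <- spec$total_pairs / sum(lambda[use])
  lambda <- lambda * scale

  counts <- with_seed(spec$seed, {
    if (spec$dispersion == 0) stats::rpois(length(lambda), lambda)
    else stats::rnbinom(length(lambda), mu = lambda, size = 1 / spec$dispersion)
  })
  counts[lambda == 0] <- 0L
  out <- bin_counts(spec$sample_id, counts, stage = "raw")
  attr(out, "lambda") <- lambda
  out
}

#' Simulate a labelled cohort
#'
#' One sample per specification; sample ids must be distinct. Returns, per
#' sample, the truth (`spec`) and the simulated counts, plus a truth table
#' for parameter-recovery tests.
#'
#' @param specs non-empty list of `sim_spec` objects with distinct
#'   `sample_id`s.
#' @param grid an annotated `bin_grid`.
#' @return list with `samples` (list of `list(spec, counts)`) and `truth`
#'   (data.frame `sample`, `template`, `tumor_fraction`, `seed`).
#' @export
simulate_cohort <- function(specs, grid) {
  if (!length(specs)) stop("empty specification list")
  ids <- vapply(specs, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample names: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- lapply(specs, function(s)
    list(spec = s, counts = simulate_counts(s, grid)))
  names(samples) <- ids
  truth <- data.frame(
    sample = ids,
    template = vapply(specs, function(s) s$profile$name, character(1)),
    tumor_fraction = vapply(specs, function(s) s$tumor_fraction, numeric(1)),
    seed = vapply(specs, function(s) s$seed, integer(1)),
    stringsAsFactors = FALSE)
  list(samples = samples, truth = truth)
}

#' Build the default study-style cohort specification
#'
#' Mirrors the shape of a small CSF liquid-biopsy study at reduced size:
#' `n_controls` copy-neutral samples plus one tumor sample per row of
#' `tumors` (template name and tumor fraction). Per-sample seeds derive from
#' `master_seed` via [derive_seed()].
#'
#' @param master_seed integer cohort seed.
#' @param n_controls number of neutral control samples (default 6).
#' @param tumors data.frame with columns `template`, `f`; default six tumors
#'   spanning tumor fractions 0.1-0.7 across the built-in templates.
#' @param ... passed to [sim_spec()] (e.g. `total_pairs`, `dispersion`).
#' @return list of `sim_spec`.
#' @export
study_cohort_specs <- function(master_seed = 1L, n_controls = 6,
                               tumors = NULL, ...) {
  if (is.null(tumors))
    tumors <- data.frame(
      template = c("gbm_7p10q", "oligo_1p19q", "lymphoma_6q",
                   "gbm_7p10q", "cdkn2ab_homdel", "focal_amp"),
      f = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7),
      stringsAsFactors = FALSE)
  specs <- list()
  idx <- 0L
  for (i in seq_len(n_controls)) {
    idx <- idx + 1L
    specs[[idx]] <- sim_spec(template_profile("neutral"), tumor_fraction = 0,
                             seed = derive_seed(master_seed, idx),
                             sample_id = sprintf("control_%02d", i), ...)
  }
  for (i in seq_len(nrow(tumors))) {
    idx <- idx + 1L
    specs[[idx]] <- sim_spec(template_profile(tumors$template[i]),
                             tumor_fraction = tumors$f[i],
                             seed = derive_seed(master_seed, idx),
                             sample_id = sprintf("tumor_%02d_%s", i, tumors$template[i]),
                             ...)
  }
  specs
}
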