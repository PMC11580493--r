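#' Build a fixed genomic bin grid
#'
#' Tiles each chromosome with windows of `bin_size` bp placed every `step` bp
#' (default `step = bin_size`, i.e. non-overlapping tiling). All counting,
#' correction and scoring downstream operate on this grid. Coordinates are
#' 0-based half-open. A partial terminal bin is kept, but flagged unusable
#' when shorter than `bin_size * min_length_fraction` so short bins cannot
#' inflate count variance.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_size window width in bp (default 5.5 Mbp).
#' @param step distance between window starts in bp; must satisfy
#'   `0 < step <= bin_size`. Defaults to `bin_size`.
#' @param genome_build label recorded on the grid (default `"HG19"`).
#' @param min_length_fraction partial terminal bins shorter than this fraction
#'   of `bin_size` are flagged unusable (default 0.5).
#' @return A `bin_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mappability`, `usable`, carrying `bin_size`, `step` and
#'   `genome_build` attributes. `gc` and `mappability` start as `NA`.
#' @export
build_bin_grid <- function(chrom_sizes, bin_size = 5500000L, step = bin_size,
                           genome_build = "HG19", min_length_fraction = 0.5) {
  if (length(chrom_sizes) == 0L) stop("no chromosomes")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be named by chromosome")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (step <= 0 || step > bin_size)
    stop("step must satisfy 0 < step <= bin_size (step > bin_size leaves gaps)")

  ord <- order(chrom_order(names(chrom_sizes)))
  chrom_sizes <- chrom_sizes[ord]

  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(0, max(0, len - 1), by = step)
    # drop windows that would start at/after the chromosome end
    starts <- starts[starts < len]
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = ch, start = starts, end = ends, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  grid$gc <- NA_real_
  grid$mappability <- NA_real_
  grid$usable <- (grid$end - grid$start) >= bin_size * min_length_fraction
  rownames(grid) <- NULL
  structure(grid,
            bin_size = as.numeric(bin_size), step = as.numeric(step),
            genome_build = genome_build,
            class = c("bin_grid", "data.frame"))
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins (%d usable) on %d chromosome(s); bin_size %g bp, step %g bp, build %s\n",
              nrow(x), sum(x$usable), length(unique(x$chrom)),
              attr(x, "bin_size"), attr(x, "step"), attr(x, "genome_build")))
  invisible(x)
}

grid_attrs <- function(grid) attributes(grid)[c("bin_size", "step", "genome_build")]

restore_grid <- function(df, template) {
  structure(df,
            bin_size = attr(template, "bin_size"),
            step = attr(template, "step"),
            genome_build = attr(template, "genome_build"),
            class = c("bin_grid", "data.frame"))
}

grid_as_granges <- function(grid) {
  GenomicRanges::GRanges(grid$chrom,
                         IRanges::IRanges(start = grid$start + 1L, end = grid$end))
}

#' Annotate per-bin GC content from sequence
#'
#' Computes the GC fraction of each bin as (G+C)/(A+C+G+T) over the bin's
#' sequence, ignoring case. Bins whose sequence exceeds `max_n_fraction` N
#' bases get a missing GC and are flagged unusable.
#'
#' @param grid a `bin_grid`.
#' @param sequence_source either a named character vector / `DNAStringSet` of
#'   chromosome sequences, or the path to a FASTA file.
#' @param max_n_fraction bins with more than this fraction of N are unusable
#'   (default 0.5).
#' @return the grid with `gc` and `usable` updated.
#' @export
annotate_gc <- function(grid, sequence_source, max_n_fraction = 0.5) {
  if (is.character(sequence_source) && length(sequence_source) == 1L &&
      file.exists(sequence_source)) {
    seqs <- Biostrings::readDNAStringSet(sequence_source)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(sequence_source)) {
    seqs <- Biostrings::DNAStringSet(toupper(sequence_source))
  } else {
    seqs <- Biostrings::DNAStringSet(sequence_source)
  }
  missing_chroms <- setdiff(unique(grid$chrom), names(seqs))
  if (length(missing_chroms))
    stop("chromosome(s) absent from sequence source: ",
         paste(missing_chroms, collapse = ", "))

  gc <- rep(NA_real_, nrow(grid))
  usable <- grid$usable
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    views <- Biostrings::Views(seqs[[ch]],
                               start = grid$start[idx] + 1L, end = grid$end[idx])
    freq <- Biostrings::letterFrequency(views, letters = c("A", "C", "G", "T", "N"))
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    nfrac <- freq[, "N"] / (grid$end[idx] - grid$start[idx])
    gc_ch <- ifelse(acgt > 0, rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt, NA_real_)
    gc_ch[nfrac > max_n_fraction] <- NA_real_
    gc[idx] <- gc_ch
  }
  grid$gc <- gc
  grid$usable <- usable & !is.na(gc)
  grid
}

#' Annotate bins from a bedGraph-style track
#'
#' Sets a per-bin value (by default `mappability`) to the length-weighted mean
#' of the overlapping track intervals; portions of a bin not covered by the
#' track contribute value 0.
#'
#' @param grid a `bin_grid`.
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open), or a bedGraph file path.
#' @param column grid column to fill (default `"mappability"`).
#' @return the grid with the column updated.
#' @export
annotate_track <- function(grid, track, column = "mappability") {
  if (is.character(track)) track <- read_bedgraph(track)
  if (!all(c("chrom", "start", "end", "value") %in% names(track)))
    stop("track must have columns chrom, start, end, value")
  if (nrow(track) && any(track$end < track$start))
    stop("track intervals with negative length")
  if (nrow(track) && any(!is.finite(track$value)))
    stop("track values must be numeric and finite")

  val <- numeric(nrow(grid))
  if (nrow(track)) {
    gr_bins <- grid_as_granges(grid)
    gr_track <- GenomicRanges::GRanges(
      track$chrom, IRanges::IRanges(start = track$start + 1L, end = track$end))
    hits <- GenomicRanges::findOverlaps(gr_bins, gr_track)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(gr_bins[S4Vectors::queryHits(hits)],
                                      gr_track[S4Vectors::subjectHits(hits)])
      w <- GenomicRanges::width(ov) * track$value[S4Vectors::subjectHits(hits)]
      sums <- tapply(w, S4Vectors::queryHits(hits), sum)
      val[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  grid[[column]] <- val / (grid$end - grid$start)
  grid
}

#' Apply bin usability filters
#'
#' Marks bins unusable when mappability falls below `min_mappability`, GC is
#' outside `gc_range`, or a blacklist covers at least `blacklist_fraction` of
#' the bin. Previously unusable bins stay unusable.
#'
#' @param grid a `bin_grid` (GC/mappability annotated as needed).
#' @param min_mappability minimum mappability in \[0,1\] (default 0).
#' @param gc_range length-2 vector `c(lo, hi)` of acceptable GC (default
#'   `c(0, 1)`).
#' @param blacklist optional data.frame `chrom,start,end` (0-based half-open)
#'   or BED path of regions to exclude.
#' @param blacklist_fraction overlap fraction at which a bin is dropped
#'   (default 0.5).
#' @return the grid with `usable` updated.
#' @export
apply_usability_filters <- function(grid, min_mappability = 0,
                                    gc_range = c(0, 1), blacklist = NULL,
                                    blacklist_fraction = 0.5) {
  if (min_mappability < 0 || min_mappability > 1)
    stop("min_mappability must be in [0,1]")
  if (length(gc_range) != 2L || gc_range[1] > gc_range[2])
    stop("gc_range must be c(lo, hi) with lo <= hi")

  usable <- grid$usable
  if (min_mappability > 0)
    usable <- usable & !is.na(grid$mappability) & grid$mappability >= min_mappability
  if (gc_range[1] > 0 || gc_range[2] < 1)
    usable <- usable & !is.na(grid$gc) &
      grid$gc >= gc_range[1] & grid$gc <= gc_range[2]

  if (!is.null(blacklist)) {
    if (is.character(blacklist)) blacklist <- read_bed(blacklist)
    if (nrow(blacklist)) {
      gr_bins <- grid_as_granges(grid)
      gr_bl <- GenomicRanges::reduce(GenomicRanges::GRanges(
        blacklist$chrom,
        IRanges::IRanges(start = blacklist$start + 1L, end = blacklist$end)))
      hits <- GenomicRanges::findOverlaps(gr_bins, gr_bl)
      if (length(hits)) {
        ov <- GenomicRanges::pintersect(gr_bins[S4Vectors::queryHits(hits)],
                                        gr_bl[S4Vectors::subjectHits(hits)])
        covered <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
        idx <- as.integer(names(covered))
        frac <- as.numeric(covered) / (grid$end[idx] - grid$start[idx])
        usable[idx[frac >= blacklist_fraction]] <- FALSE
      }
    }
  }
  grid$usable <- usable
  grid
}

#' Autosomal-bin indicator
#'
#' @param grid a `bin_grid`.
#' @return logical vector, `TRUE` for bins on chromosomes 1..22.
#' @export
is_autosome <- function(grid) {
  !(sub("^chr", "", grid$chrom) %in% c("X", "Y"))
}

# which bins enter normalization/scoring
scoring_bins <- function(grid, include_sex_chromosomes = FALSE) {
  grid$usable & (include_sex_chromosomes | is_autosome(grid))
}
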