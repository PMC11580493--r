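# Shared fixtures: tiny grids, a flat-annotation helper, an independent
# naive metrics oracle, and an in-code SAM writer for the counting path.

# single-chromosome toy grid; chrom "1" so bins count as autosomal
toy_grid <- function(len = 11e6, bin = 5.5e6, chrom = "1", step = bin) {
  build_bin_grid(stats::setNames(len, chrom), bin_size = bin, step = step)
}

# constant annotations: nothing for the correction to do
flat_annotation <- function(grid, gc = 0.45, mappability = 1) {
  grid$gc <- gc
  grid$mappability <- mappability
  grid
}

annotated_hg19_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- annotate_synthetic(build_bin_grid(hg19_chrom_sizes()), seed = 424242)
    cache
  }
})

# independent oracle: per-bin loop, no vectorized shortcuts
naive_metrics <- function(log2r, amp_thr = 0.1, del_thr = -0.1, min_bins = 5) {
  cni <- 0; n_ab <- 0L
  for (v in log2r) {
    if (is.na(v)) next
    if (v > amp_thr || v < del_thr) {
      cni <- cni + abs(v)
      n_ab <- n_ab + 1L
    }
  }
  list(cni_score = cni, aberrant_bin_count = n_ab,
       scna_positive = n_ab >= min_bins,
       tumor_fraction_score = if (n_ab > 0) cni / n_ab else NA_real_)
}

# minimal paired-end SAM: one row per mate; seq/qual omitted ("*")
write_test_sam <- function(path, chrom_sizes, pairs) {
  # pairs: data.frame(qname, chrom, pos1, pos2, mapq, dup = FALSE)
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), as.integer(chrom_sizes)))
  recs <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    dupbit <- if (isTRUE(p$dup)) 1024L else 0L
    f1 <- 99L + dupbit   # paired, proper, mate reverse, first
    f2 <- 147L + dupbit  # paired, proper, reverse, second
    recs <- c(recs,
              sprintf("%s\t%d\t%s\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
                      p$qname, f1, p$chrom, p$pos1, p$mapq, p$pos2, p$pos2 - p$pos1 + 50L),
              sprintf("%s\t%d\t%s\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
                      p$qname, f2, p$chrom, p$pos2, p$mapq, p$pos1, -(p$pos2 - p$pos1 + 50L)))
  }
  # SAM must be coordinate sorted for asBam
  ord <- order(vapply(strsplit(recs, "\t"), function(x) as.integer(x[4]), integer(1)))
  writeLines(c(lines, recs[ord]), path)
  path
}
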