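#' HG19 chromosome sizes
#'
#' Lengths of the 24 human chromosomes (GRCh37/HG19), the reference build the
#' pipeline defaults to. Chromosome names are plain ("1".."22", "X", "Y").
#'
#' @param include_sex include the X and Y chromosomes (default `TRUE`).
#' @return Named numeric vector of chromosome lengths in bp, in natural order.
#' @export
hg19_chrom_sizes <- function(include_sex = TRUE) {
  sizes <- c(
    "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
    "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
    "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
    "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
    "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
    "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
  )
  if (!include_sex) sizes <- sizes[setdiff(names(sizes), c("X", "Y"))]
  sizes
}

# HG19 centromere gap boundaries (UCSC gap/cytoband "acen" extent).
# p arm = [0, cen_start); q arm = [cen_end, chrom length).
hg19_centromeres <- function() {
  data.frame(
    chrom = c(as.character(1:22), "X", "Y"),
    cen_start = c(
      121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
      58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
      16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
      24681782, 26369569, 11288129, 13000000, 58632012, 10104553
    ),
    cen_end = c(
      124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
      61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
      19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
      27681782, 29369569, 14288129, 16000000, 61632012, 13104553
    ),
    stringsAsFactors = FALSE
  )
}

#' HG19 chromosome-arm table
#'
#' Arm intervals (p and q per chromosome) derived from the HG19 centromere
#' gaps, in the `chrom start end arm` layout expected by [arm_calls()].
#' Coordinates are 0-based half-open; the centromere gap belongs to neither
#' arm.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `arm`.
#' @export
hg19_arm_table <- function() {
  cen <- hg19_centromeres()
  len <- hg19_chrom_sizes()[cen$chrom]
  p <- data.frame(chrom = cen$chrom, start = 0, end = cen$cen_start,
                  arm = paste0(cen$chrom, "p"), stringsAsFactors = FALSE)
  q <- data.frame(chrom = cen$chrom, start = cen$cen_end, end = unname(len),
                  arm = paste0(cen$chrom, "q"), stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out <- out[order(match(out$chrom, cen$chrom), out$start), ]
  rownames(out) <- NULL
  out
}

#' Natural chromosome ordering
#'
#' Orders chromosome names 1..22, X, Y (with or without a "chr" prefix);
#' unknown names sort after, alphabetically.
#'
#' @param chroms character vector of chromosome names.
#' @return integer rank usable for sorting.
#' @export
chrom_order <- function(chroms) {
  canon <- sub("^chr", "", as.character(chroms))
  ref <- c(as.character(1:22), "X", "Y")
  idx <- match(canon, ref)
  idx[is.na(idx)] <- length(ref) + rank(canon[is.na(idx)], ties.method = "min")
  idx
}
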