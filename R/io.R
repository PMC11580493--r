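# Readers and writers for the pipeline's plain-text formats. All genomic
# coordinates on disk are 0-based half-open (BED convention); validation is
# strict and errors name the offending line.

read_tsv_checked <- function(path, col_names, col_classes, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch({
    if (header)
      utils::read.table(path, sep = "\t", header = TRUE,
                        colClasses = col_classes, stringsAsFactors = FALSE,
                        comment.char = "", quote = "")
    else
      utils::read.table(path, sep = "\t", header = FALSE, col.names = col_names,
                        colClasses = col_classes, stringsAsFactors = FALSE,
                        comment.char = "", quote = "")
  }, error = function(e) stop("malformed file ", path, ": ", conditionMessage(e)))
  if (header) {
    if (!all(col_names %in% names(df)))
      stop("file ", path, " lacks required column(s): ",
           paste(setdiff(col_names, names(df)), collapse = ", "))
    df <- df[col_names]
  }
  df
}

check_intervals <- function(df, path) {
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$end <= df$start)
  if (length(bad))
    stop("invalid interval in ", path, " at data line ", bad[1],
         " (need 0 <= start < end)")
  df
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two-column TSV `chrom length`.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "length"),
                         c("character", "numeric"), header = FALSE)
  if (any(!is.finite(df$length) | df$length <= 0))
    stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Read a 3+ column BED file
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  first <- utils::read.table(path, sep = "\t", header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE, comment.char = "")
  ncol <- ncol(first)
  cols <- c("chrom", "start", "end", if (ncol >= 4) "name")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")[, seq_along(cols)]
  names(df) <- cols
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  check_intervals(df, path)
}

#' Write a BED file
#' @param df data.frame with `chrom`, `start`, `end` and optional extra columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' Four columns `chrom start end value`, 0-based half-open; `track` header
#' lines are skipped.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|#|browser)", lines) & nzchar(lines)
  if (!any(keep))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  df <- utils::read.table(text = lines[keep], sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  check_intervals(df, path)
}

#' Write a bedGraph track
#' @param df data.frame `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @param track_name optional name for a `track` header line.
#' @export
write_bedgraph <- function(df, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  utils::write.table(df[c("chrom", "start", "end", "value")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bin-annotation table
#'
#' TSV with header `chrom start end gc mappability usable`; first three
#' columns are BED-compatible.
#'
#' @param grid a `bin_grid`.
#' @param path output path.
#' @export
write_bin_grid <- function(grid, path) {
  df <- as.data.frame(grid)[c("chrom", "start", "end", "gc", "mappability", "usable")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_size=%g step=%g genome_build=%s",
                     attr(grid, "bin_size"), attr(grid, "step"),
                     attr(grid, "genome_build")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin-annotation table written by [write_bin_grid()]
#' @param path file path.
#' @return a `bin_grid`.
#' @export
read_bin_grid <- function(path) {
  lines <- readLines(path)
  meta <- list(bin_size = NA_real_, step = NA_real_, genome_build = "HG19")
  if (length(lines) && grepl("^#", lines[1])) {
    kv <- regmatches(lines[1], gregexpr("[A-Za-z_]+=[^ ]+", lines[1]))[[1]]
    for (item in kv) {
      key <- sub("=.*", "", item); val <- sub(".*=", "", item)
      meta[[key]] <- if (key == "genome_build") val else as.numeric(val)
    }
    lines <- lines[-1]
  }
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "gc", "mappability", "usable")
  if (!all(need %in% names(df)))
    stop("bin table ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  check_intervals(df, path)
  if (is.na(meta$bin_size)) meta$bin_size <- max(df$end - df$start)
  if (is.na(meta$step)) meta$step <- meta$bin_size
  structure(df[need], bin_size = meta$bin_size, step = meta$step,
            genome_build = meta$genome_build,
            class = c("bin_grid", "data.frame"))
}

#' Write per-bin counts
#'
#' TSV `chrom start end count` aligned to the bin grid.
#'
#' @param counts a `bin_counts` object.
#' @param grid the `bin_grid` the counts live on.
#' @param path output path.
#' @export
write_counts <- function(counts, grid, path) {
  stopifnot(inherits(counts, "bin_counts"))
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   count = counts$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read per-bin counts against a grid
#'
#' The file's bin boundaries must match the grid exactly; the first mismatch
#' is reported by line.
#'
#' @param path count TSV (`chrom start end count`).
#' @param grid the expected `bin_grid`.
#' @param sample_id sample label (default: file name without extension).
#' @param stage `"raw"` or `"corrected"` (default `"raw"`).
#' @return a `bin_counts` object.
#' @export
read_counts <- function(path, grid, sample_id = NULL, stage = "raw") {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "count"),
                         NA, header = TRUE)
  df$chrom <- as.character(df$chrom)
  check_intervals(df, path)
  if (nrow(df) != nrow(grid))
    stop("count file ", path, " has ", nrow(df), " bins; grid has ", nrow(grid))
  mism <- which(df$chrom != grid$chrom | df$start != grid$start | df$end != grid$end)
  if (length(mism))
    stop("count file ", path, " does not match grid: first mismatch at data line ",
         mism[1], " (file ", df$chrom[mism[1]], ":", df$start[mism[1]], "-",
         df$end[mism[1]], ", grid ", grid$chrom[mism[1]], ":",
         grid$start[mism[1]], "-", grid$end[mism[1]], ")")
  if (any(df$count < 0, na.rm = TRUE)) stop("negative counts in ", path)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  bin_counts(sample_id, df$count, stage = stage)
}

#' Write per-sample metrics as JSON
#'
#' @param metrics an `scna_metrics` object.
#' @param path output path.
#' @param qc optional `qc_metrics` list merged under `"qc"`.
#' @param flags optional `diagnostic_flags` list merged under `"flags"`.
#' @export
write_metrics_json <- function(metrics, path, qc = NULL, flags = NULL) {
  x <- unclass(metrics)
  if (!is.null(qc)) x$qc <- unclass(qc)
  if (!is.null(flags)) x$flags <- unclass(flags)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a metrics JSON written by [write_metrics_json()]
#' @param path file path.
#' @return named list.
#' @export
read_metrics_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a flat key=value pipeline configuration file
#'
#' Unknown keys error; values are coerced to the type of the default. See
#' [pipeline_config()] for the keys and defaults.
#'
#' @param path file path (lines `key = value`; `#` comments allowed).
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path) {
  defaults <- pipeline_config()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE))
      stop("malformed config line ", i, ": ", lines[i])
    key <- trimws(sub("=.*$", "", lines[i]))
    val <- trimws(sub("^[^=]*=", "", lines[i]))
    if (!key %in% names(defaults))
      stop("unknown config key: ", key)
    proto <- defaults[[key]]
    overrides[[key]] <-
      if (is.logical(proto)) as.logical(val)
      else if (is.numeric(proto)) as.numeric(val)
      else val
  }
  do.call(pipeline_config, overrides)
}

#' Write a pipeline configuration file
#' @param config a `pipeline_config` list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", if (is.numeric(v)) format(v, scientific = FALSE, digits = 15) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
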