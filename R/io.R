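#' Validate a beta-value matrix
#'
#' A beta matrix stores per-probe methylation fractions (methylated intensity
#' over total intensity) with probes in rows and samples in columns. All
#' non-missing values must lie in \[0, 1\] and both identifier sets must be
#' unique. `NA` entries are permitted and are excluded pairwise downstream.
#'
#' @param x Numeric matrix, probes x samples, with rownames (probe ids) and
#'   colnames (sample ids).
#' @return `x`, invisibly classed as it came in, after validation.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("beta matrix must carry probe ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (%g)",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
                 x[bad[1, , drop = FALSE]]))
  }
  invisible(x)
}

#' Read / write a beta matrix as delimited text
#'
#' The on-disk format is a header row of sample ids and a probe-id first
#' column named `probe_id`.
#'
#' @param path File path.
#' @param delimiter Field separator (default tab).
#' @return `read_beta_matrix()` returns a validated numeric matrix
#'   (probes x samples); `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("beta matrix file needs a probe_id column plus samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_beta_matrix(m)
  m
}

#' @rdname read_beta_matrix
#' @param x Beta matrix to write.
#' @export
write_beta_matrix <- function(x, path, delimiter = "\t") {
  validate_beta_matrix(x)
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `age` (years, finite and >= 0), `sex`
#' (`male`/`female`), `batch`, `group` (`control` or a disorder label).
#'
#' @param path File path to delimited text.
#' @param delimiter Field separator.
#' @return A data.frame with the required columns, one row per sample.
#' @export
read_sample_sheet <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet Data frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "age", "sex", "batch", "group")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0)
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sample sheet")
  if (any(!is.finite(sheet$age)) || any(sheet$age < 0))
    stop("ages must be finite and >= 0")
  if (!all(sheet$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$batch <- as.character(sheet$batch)
  sheet$group <- as.character(sheet$group)
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path, delimiter = "\t") {
  utils::write.table(validate_sample_sheet(sheet), path, sep = delimiter,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## --- genomic interval / signal I/O -----------------------------------------
## Internal convention: 0-based half-open coordinates (the BED convention),
## stored in plain data frames. rtracklayer handles the file formats and the
## 1-based GRanges representation; the conversion happens once, at load.

#' Read genomic intervals from a BED file
#'
#' Intervals are returned in 0-based half-open coordinates, sorted by
#' chromosome and start.
#'
#' @param path Path to a BED file (3+ columns).
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end,
                    stringsAsFactors = FALSE)
  if (!is.null(df$name)) out$name <- as.character(df$name)
  validate_intervals(out)
}

#' @rdname read_intervals
#' @param intervals Interval data.frame to validate.
#' @export
validate_intervals <- function(intervals) {
  if (!all(c("chrom", "start", "end") %in% names(intervals)))
    stop("intervals need chrom, start, end columns")
  if (any(is.na(intervals$start)) || any(is.na(intervals$end)))
    stop("NA coordinates in intervals")
  if (any(intervals$start < 0)) stop("negative coordinates in intervals")
  if (any(intervals$start >= intervals$end)) stop("intervals require start < end")
  o <- order(intervals$chrom, intervals$start, intervals$end)
  out <- intervals[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a continuous signal track from a bedGraph file
#'
#' @param path Path to a bedGraph file.
#' @param statistic_label Label describing the statistic carried by the track
#'   (e.g. `"fold-change"`, `"NRC"`, `"WTS"`, `"sur+"`, `"sur-"`, `"generic"`).
#' @return data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open), sorted, with attribute `statistic_label`. Intervals
#'   must not overlap within a chromosome.
#' @export
read_signal_track <- function(path, statistic_label = "generic") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end,
                    value = as.numeric(df$score), stringsAsFactors = FALSE)
  validate_signal_track(out, statistic_label)
}

#' @rdname read_signal_track
#' @param track Signal data.frame to validate.
#' @export
validate_signal_track <- function(track, statistic_label = "generic") {
  if (!all(c("chrom", "start", "end", "value") %in% names(track)))
    stop("signal track needs chrom, start, end, value columns")
  if (any(!is.finite(track$value))) stop("non-finite signal values")
  out <- validate_intervals(track[, c("chrom", "start", "end")])
  out$value <- track$value[order(track$chrom, track$start, track$end)]
  by_chr <- split(out, out$chrom)
  for (ch in by_chr) {
    if (nrow(ch) > 1 && any(ch$start[-1] < ch$end[-nrow(ch)]))
      stop("overlapping intervals within chromosome ", ch$chrom[1])
  }
  attr(out, "statistic_label") <- statistic_label
  out
}

#' @rdname read_signal_track
#' @export
write_signal_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname read_intervals
#' @export
write_intervals <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  utils::write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read probe genomic coordinates
#'
#' @param path Tab-delimited file with columns `probe_id`, `chrom`, `pos`
#'   (0-based CpG coordinate).
#' @param one_based Set to `TRUE` for manifests using 1-based positions; they
#'   are converted to the internal 0-based convention at load.
#' @return data.frame `probe_id`, `chrom`, `pos`.
#' @export
read_probe_coordinates <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("probe_id", "chrom", "pos"), names(df))
  if (length(missing) > 0)
    stop("probe coordinate file missing column(s): ",
         paste(missing, collapse = ", "))
  if (one_based) df$pos <- df$pos - 1L
  validate_probe_coordinates(df)
}

#' @rdname read_probe_coordinates
#' @param coords Coordinate data.frame to validate.
#' @export
validate_probe_coordinates <- function(coords) {
  if (anyDuplicated(coords$probe_id)) stop("duplicate probe ids in coordinates")
  if (any(is.na(coords$pos)) || any(coords$pos < 0))
    stop("probe positions must be non-negative and non-missing")
  coords$probe_id <- as.character(coords$probe_id)
  coords$chrom <- as.character(coords$chrom)
  coords
}

#' @rdname read_probe_coordinates
#' @export
write_probe_coordinates <- function(coords, path) {
  utils::write.table(coords[, c("probe_id", "chrom", "pos")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' QC intensity filter for methylation arrays
#'
#' A sample passes quality control when
#' `(median(log2 M) + median(log2 U)) / 2 >= threshold`, where the medians run
#' over all array probes of that sample. Zero intensities are raised to
#' `floor` before taking logs; the original handling of zeros upstream of this
#' statistic is not standardized, so the floor is explicit and configurable.
#'
#' @param methylated,unmethylated Numeric matrices (probes x samples) of
#'   methylated / unmethylated fluorescence intensities, same shape.
#' @param threshold Pass threshold in log2 units (default 10.5).
#' @param floor Value replacing intensities below it before log2 (default 1).
#' @return data.frame with `sample_id`, `statistic`, `pass`, `reason`.
#' @export
qc_intensity_filter <- function(methylated, unmethylated, threshold = 10.5,
                                floor = 1) {
  if (!identical(dim(methylated), dim(unmethylated)))
    stop("methylated and unmethylated matrices must have identical shapes")
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    stop("negative intensities")
  ids <- colnames(methylated)
  if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(methylated)))
  stat <- numeric(ncol(methylated))
  pass <- logical(ncol(methylated))
  reason <- character(ncol(methylated))
  for (j in seq_len(ncol(methylated))) {
    m <- methylated[, j]
    u <- unmethylated[, j]
    if (all(m == 0, na.rm = TRUE) && all(u == 0, na.rm = TRUE)) {
      stat[j] <- NA_real_
      pass[j] <- FALSE
      reason[j] <- "degenerate intensities"
      next
    }
    s <- (stats::median(log2(pmax(m, floor)), na.rm = TRUE) +
            stats::median(log2(pmax(u, floor)), na.rm = TRUE)) / 2
    stat[j] <- s
    pass[j] <- s >= threshold
    reason[j] <- if (pass[j]) "" else "below intensity threshold"
  }
  data.frame(sample_id = ids, statistic = stat, pass = pass, reason = reason,
             stringsAsFactors = FALSE)
}
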