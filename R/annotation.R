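#' Mean track signal in a window around each probe
#'
#' For every probe, averages a piecewise-constant signal track over the
#' window of +/- `half_width` bp around the CpG coordinate (2*half_width + 1
#' bases). Bases inside the track's chromosome extent but not covered by any
#' interval contribute 0 by default (the bedGraph sparsity convention); set
#' `uncovered = "exclude"` to average over covered bases only. Windows are
#' truncated at the chromosome bounds (position 0 and the last covered base).
#' Probes on chromosomes absent from the track get `NA`.
#'
#' @param track Signal track data.frame (`chrom`, `start`, `end`, `value`,
#'   0-based half-open; see [read_signal_track()]).
#' @param coords Probe coordinates (`probe_id`, `chrom`, `pos`).
#' @param half_width Window half-width in bp (default 200).
#' @param uncovered `"zero"` (default) or `"exclude"`.
#' @return Named numeric vector, probe id -> window mean.
#' @export
window_mean_signal <- function(track, coords, half_width = 200,
                               uncovered = c("zero", "exclude")) {
  uncovered <- match.arg(uncovered)
  if (half_width <= 0) stop("half_width must be positive")
  coords <- validate_probe_coordinates(coords)
  out <- stats::setNames(rep(NA_real_, nrow(coords)), coords$probe_id)
  for (ch in unique(coords$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0) next                    # chromosome absent -> NA
    chrom_end <- max(tr$end)
    idx <- which(coords$chrom == ch)
    pos <- coords$pos[idx]
    lo <- pmax(0, pos - half_width)
    hi <- pmin(chrom_end, pos + half_width + 1)
    ok <- hi > lo
    ir_t <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
    ir_w <- IRanges::IRanges(start = lo[ok] + 1L, end = hi[ok])
    hits <- IRanges::findOverlaps(ir_w, ir_t)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ow <- pmin(hi[ok][qi], tr$end[si]) - pmax(lo[ok][qi], tr$start[si])
    sums <- numeric(sum(ok))
    covs <- numeric(sum(ok))
    for (h in seq_along(qi)) {                 # accumulate per window
      sums[qi[h]] <- sums[qi[h]] + ow[h] * tr$value[si[h]]
      covs[qi[h]] <- covs[qi[h]] + ow[h]
    }
    denom <- if (uncovered == "zero") hi[ok] - lo[ok] else covs
    vals <- ifelse(denom > 0, sums / denom, NA_real_)
    out[idx[ok]] <- vals
  }
  out
}

#' Z-score a vector of signal values
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation, the
#' standardization applied to each continuous genomic feature before
#' aggregation or comparison.
#'
#' @param values Numeric vector (length >= 2).
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need >= 2 values to z-score")
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("zero standard deviation; cannot z-score")
  (values - mean(values, na.rm = TRUE)) / s
}

#' Aggregate replicate z-scored signals into one feature
#'
#' Biological replicates of the same genomic feature are combined by taking
#' the per-probe mean of their z-scores (producing e.g. the "normalised fold
#' change", NFC, for ChIP-seq features).
#'
#' @param z_list List (or matrix columns) of z-scored per-probe vectors,
#'   aligned on the same probes.
#' @return Named numeric vector of per-probe means.
#' @export
aggregate_replicates <- function(z_list) {
  m <- if (is.matrix(z_list)) z_list else do.call(cbind, z_list)
  if (is.null(m) || ncol(m) == 0) stop("no replicates supplied")
  rowMeans(m)
}

#' Normalised RNA expression (NRE) around probes
#'
#' Strand-specific "signal of unique reads" tracks are window-averaged around
#' each probe, summed across strands, transformed as `log2(1 + sur+ + sur-)`,
#' and the result z-scored across probes.
#'
#' @param sur_plus,sur_minus Signal tracks for the + and - strands
#'   (non-negative values).
#' @param coords Probe coordinates.
#' @param half_width Window half-width in bp (default 200).
#' @return data.frame `probe_id`, `rna` (log2 scale, before scaling), `nre`
#'   (z-scored).
#' @export
rna_signal <- function(sur_plus, sur_minus, coords, half_width = 200) {
  if (any(sur_plus$value < 0) || any(sur_minus$value < 0))
    stop("RNA signal tracks must be non-negative")
  wp <- window_mean_signal(sur_plus, coords, half_width)
  wm <- window_mean_signal(sur_minus, coords, half_width)
  rna <- log2(1 + wp + wm)
  s <- stats::sd(rna, na.rm = TRUE)
  nre <- if (is.na(s) || s == 0) rep(NA_real_, length(rna)) else zscore(rna)
  data.frame(probe_id = coords$probe_id, rna = as.numeric(rna),
             nre = as.numeric(nre), stringsAsFactors = FALSE)
}

#' Classify probes by CpG-island context
#'
#' Labels each probe `island` when it lies inside a (merged) CGI, `shore`
#' when the distance to the nearest CGI boundary is in (0, 2000\] bp, `shelf`
#' in (2000, 4000\] bp, and `open-sea` otherwise. A distance of exactly
#' 2000 bp is a shore and exactly 4000 bp a shelf.
#'
#' @param coords Probe coordinates.
#' @param cgis Interval set of CpG islands (merged if overlapping).
#' @return Named character vector, probe id -> label.
#' @export
classify_cgi_context <- function(coords, cgis) {
  coords <- validate_probe_coordinates(coords)
  cgis <- merge_intervals(validate_intervals(cgis))
  out <- stats::setNames(rep("open-sea", nrow(coords)), coords$probe_id)
  for (ch in unique(coords$chrom)) {
    cg <- cgis[cgis$chrom == ch, , drop = FALSE]
    idx <- which(coords$chrom == ch)
    if (nrow(cg) == 0) next
    pos <- coords$pos[idx]
    inside <- vapply(pos, function(p) any(p >= cg$start & p < cg$end),
                     logical(1))
    bounds <- sort(c(cg$start, cg$end))
    d <- vapply(pos, function(p) min(abs(p - bounds)), numeric(1))
    lab <- ifelse(inside, "island",
                  ifelse(d <= 2000, "shore",
                         ifelse(d <= 4000, "shelf", "open-sea")))
    out[idx] <- lab
  }
  out
}

# merge overlapping/adjacent-overlapping intervals within chromosomes
merge_intervals <- function(intervals) {
  pieces <- lapply(split(intervals, intervals$chrom), function(ch) {
    ch <- ch[order(ch$start), , drop = FALSE]
    s <- ch$start[1]; e <- ch$end[1]
    outs <- list()
    if (nrow(ch) > 1) for (i in 2:nrow(ch)) {
      if (ch$start[i] <= e) e <- max(e, ch$end[i])
      else { outs[[length(outs) + 1]] <- c(s, e); s <- ch$start[i]; e <- ch$end[i] }
    }
    outs[[length(outs) + 1]] <- c(s, e)
    m <- do.call(rbind, outs)
    data.frame(chrom = ch$chrom[1], start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Does each probe overlap an interval set?
#'
#' Point containment under the 0-based half-open convention: position `p`
#' lies in `[start, end)` iff `start <= p < end`.
#'
#' @param coords Probe coordinates.
#' @param intervals Interval set (e.g. gene bodies, chromatin states).
#' @return Named logical vector, probe id -> overlaps.
#' @export
overlap_categorical <- function(coords, intervals) {
  coords <- validate_probe_coordinates(coords)
  intervals <- validate_intervals(intervals)
  out <- stats::setNames(rep(FALSE, nrow(coords)), coords$probe_id)
  for (ch in unique(coords$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    idx <- which(coords$chrom == ch)
    ir_p <- IRanges::IRanges(start = coords$pos[idx] + 1L, width = 1L)
    ir_i <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    out[idx] <- IRanges::overlapsAny(ir_p, ir_i)
  }
  out
}

#' Fisher enrichment of a binary feature in a probe subset
#'
#' The control set is the universe minus the subset (never double-counted),
#' yielding the 2x2 table (subset-with, subset-without; control-with,
#' control-without). The odds ratio is the sample OR `(a d)/(b c)`, with the
#' Haldane 0.5 correction added to every cell iff any cell is zero (flagged
#' `degenerate`). The two-sided p-value sums the hypergeometric point
#' probabilities of all tables with the observed margins that are no more
#' likely than the observed one.
#'
#' @param subset Character vector of probe ids (must be contained in
#'   `universe`).
#' @param universe Character vector of all background probe ids. Choose it
#'   explicitly (e.g. the clock-training 21K probes vs the full array) — the
#'   appropriate background differs between analyses.
#' @param feature Named logical vector over the universe (probe id -> has
#'   feature).
#' @param alpha Significance level after Bonferroni correction (default 0.01).
#' @param n_tests Number of features tested in the batch (Bonferroni divisor).
#' @return list of class `enrichment_result`: `table` (2x2), `odds_ratio`,
#'   `p`, `p_adjusted`, `significant`, `degenerate`.
#' @export
enrichment_test <- function(subset, universe, feature, alpha = 0.01,
                            n_tests = 1) {
  if (length(subset) == 0) stop("empty subset")
  if (!all(subset %in% universe)) stop("subset must be contained in universe")
  control <- setdiff(universe, subset)
  if (length(control) == 0) stop("empty control set (subset equals universe)")
  f <- feature[universe]
  if (anyNA(f)) stop("feature must be defined for every universe probe")
  a <- sum(f[subset]); b <- length(subset) - a
  cc <- sum(f[control]); d <- length(control) - cc
  degenerate <- any(c(a, b, cc, d) == 0)
  or <- if (degenerate) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  # two-sided hypergeometric point-probability p-value
  m <- a + cc; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p0 <- stats::dhyper(a, m, nn, k)
  p <- sum(probs[probs <= p0 * (1 + 1e-7)])
  p <- min(1, p)
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(c("subset", "control"),
                                c("with", "without")))
  structure(list(table = tab, odds_ratio = or, p = p,
                 p_adjusted = min(1, p * n_tests),
                 significant = min(1, p * n_tests) < alpha,
                 degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher enrichment: OR = %.3f, p = %.3g (adjusted %.3g)%s\n",
              x$odds_ratio, x$p, x$p_adjusted,
              if (x$degenerate) " [Haldane-corrected]" else ""))
  print(x$table)
  invisible(x)
}

#' Compare a continuous feature between a probe subset and a control set
#'
#' Two-sided Wilcoxon rank-sum comparison (same exactness rule as the
#' disorder screen), reported with group medians and sizes, matching how
#' continuous genomic features are contrasted between DMP subsets and their
#' background.
#'
#' @param subset_values,control_values Numeric vectors.
#' @return list: `p`, `median_subset`, `median_control`, `n_subset`,
#'   `n_control`, `all_tied`.
#' @export
compare_continuous <- function(subset_values, control_values) {
  if (length(subset_values) == 0 || length(control_values) == 0)
    stop("both groups must be non-empty")
  all_tied <- length(unique(c(subset_values, control_values))) == 1
  p <- if (all_tied) 1 else rank_sum_test(subset_values, control_values)$p
  list(p = p,
       median_subset = stats::median(subset_values),
       median_control = stats::median(control_values),
       n_subset = length(subset_values),
       n_control = length(control_values),
       all_tied = all_tied)
}
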